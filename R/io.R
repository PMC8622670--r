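# Plain-text readers/writers for the tabular exchange formats: traces as a
# cells x frames TSV, centroids / intervals / protocol / behavior as small
# column tables. All files are tab-separated with a header.

#' Write a calcium session to a directory
#'
#' Writes `traces.tsv` (cells x frames), `centroids.tsv`, `meta.tsv` and, if
#' present, `protocol.tsv`.
#'
#' @param sess a [calcium_session()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_calcium_session <- function(sess, dir) {
  stopifnot(inherits(sess, "calcium_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sess$traces, file.path(dir, "traces.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(sess$centroids, file.path(dir, "centroids.tsv"),
                     sep = "\t", row.names = FALSE)
  meta <- data.frame(frame_hz = sess$frame_hz, genotype = sess$genotype,
                     fov_id = sess$fov_id)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE)
  if (!is.null(sess$protocol))
    utils::write.table(sess$protocol, file.path(dir, "protocol.tsv"),
                       sep = "\t", row.names = FALSE)
  invisible(dir)
}

#' Read a calcium session from a directory
#'
#' Counterpart of [write_calcium_session()].
#'
#' @param dir directory containing `traces.tsv`, `centroids.tsv`, `meta.tsv`
#'   and optionally `protocol.tsv`
#' @return a [calcium_session()]
#' @export
read_calcium_session <- function(dir) {
  traces <- as.matrix(utils::read.table(file.path(dir, "traces.tsv"),
                                        sep = "\t"))
  dimnames(traces) <- NULL
  centroids <- utils::read.table(file.path(dir, "centroids.tsv"),
                                 sep = "\t", header = TRUE)
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE)
  proto_path <- file.path(dir, "protocol.tsv")
  protocol <- if (file.exists(proto_path))
    utils::read.table(proto_path, sep = "\t", header = TRUE) else NULL
  calcium_session(traces, centroids, meta$frame_hz, meta$genotype,
                  meta$fov_id, protocol)
}

#' Write an LFP recording to a directory
#'
#' Writes `signal.tsv` (one voltage column), `intervals.tsv` and `meta.tsv`.
#'
#' @param rec an [lfp_recording()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_lfp_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "lfp_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(voltage_mv = rec$samples),
                     file.path(dir, "signal.tsv"), sep = "\t",
                     row.names = FALSE)
  utils::write.table(rec$intervals, file.path(dir, "intervals.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(data.frame(fs_hz = rec$fs_hz,
                                subject_id = rec$subject_id,
                                genotype = rec$genotype),
                     file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE)
  invisible(dir)
}

#' Read an LFP recording from a directory
#'
#' Counterpart of [write_lfp_recording()].
#'
#' @param dir directory containing `signal.tsv`, `intervals.tsv`, `meta.tsv`
#' @return an [lfp_recording()]
#' @export
read_lfp_recording <- function(dir) {
  sig <- utils::read.table(file.path(dir, "signal.tsv"), sep = "\t",
                           header = TRUE)
  intervals <- utils::read.table(file.path(dir, "intervals.tsv"), sep = "\t",
                                 header = TRUE)
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE)
  lfp_recording(sig$voltage_mv, meta$fs_hz, intervals, meta$subject_id,
                meta$genotype)
}
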