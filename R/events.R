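#' Calcium imaging session container
#'
#' ROI fluorescence traces from one field of view (FOV), with soma centroid
#' coordinates in micrometers, the acquisition frame rate, and an optional
#' stimulus protocol.
#'
#' @param traces numeric matrix, cells x frames
#' @param centroids data.frame with columns `cell_id`, `x_um`, `y_um`
#'   (one row per trace)
#' @param frame_hz acquisition rate (frames/s), default 30
#' @param genotype `"WT"` or `"KO"`
#' @param fov_id field-of-view identifier
#' @param protocol optional data.frame with columns `trial_id`, `stimulus`
#'   (`"odor"` or `"oil"`), `onset_s`, `duration_s`
#' @return an object of class `calcium_session`
#' @export
calcium_session <- function(traces, centroids = NULL, frame_hz = 30,
                            genotype = "WT", fov_id = "fov1",
                            protocol = NULL) {
  traces <- rbind(traces)  # promote a single trace to a 1-row matrix
  dimnames(traces) <- NULL
  stopifnot(is.numeric(traces), ncol(traces) >= 2, frame_hz > 0)
  if (is.null(centroids)) {
    centroids <- data.frame(cell_id = seq_len(nrow(traces)),
                            x_um = 0, y_um = 0)
  }
  stopifnot(nrow(centroids) == nrow(traces),
            all(c("cell_id", "x_um", "y_um") %in% names(centroids)))
  if (!is.null(protocol)) {
    stopifnot(all(c("trial_id", "stimulus", "onset_s", "duration_s") %in%
                    names(protocol)),
              all(protocol$stimulus %in% c("odor", "oil")))
    if (is.unsorted(protocol$onset_s))
      stop("protocol onsets must be ascending")
    if (nrow(protocol) > 1 &&
        any(protocol$onset_s[-1] <
              (protocol$onset_s + protocol$duration_s)[-nrow(protocol)]))
      stop("protocol trials overlap")
  }
  structure(list(traces = traces, centroids = centroids,
                 frame_hz = as.numeric(frame_hz),
                 genotype = genotype, fov_id = fov_id, protocol = protocol,
                 filtered = NULL, zscored = NULL, excluded = NULL),
            class = "calcium_session")
}

#' @export
print.calcium_session <- function(x, ...) {
  cat(sprintf("<calcium_session> %s (%s): %d cells x %d frames at %g fps%s\n",
              x$fov_id, x$genotype, nrow(x$traces), ncol(x$traces),
              x$frame_hz,
              if (is.null(x$protocol)) ", spontaneous" else
                sprintf(", %d stimulus trials", nrow(x$protocol))))
  invisible(x)
}

#' Pre-process fluorescence traces
#'
#' Band-pass filters every trace 0.005-0.8 Hz (zero-phase, 5th-order
#' Butterworth response) to remove detection noise and slow drifts, and
#' stores a per-cell z-scored copy alongside. Cells whose filtered trace is
#' constant have an undefined z-score; they are flagged in `$excluded` and
#' their z-scored rows are set to 0.
#'
#' @param sess a [calcium_session()]
#' @param lo_hz,hi_hz filter band edges (defaults 0.005 and 0.8 Hz)
#' @param order filter order (default 5)
#' @return the session with `$filtered`, `$zscored` and `$excluded` filled
#' @export
preprocess_traces <- function(sess, lo_hz = 0.005, hi_hz = 0.8, order = 5) {
  stopifnot(inherits(sess, "calcium_session"))
  n_frames <- ncol(sess$traces)
  if (n_frames / sess$frame_hz < 1 / lo_hz)
    warning("trace shorter than the slowest filter time constant (",
            round(1 / lo_hz), " s); low-frequency response is approximate")
  filt <- t(apply(sess$traces, 1, filter_bandpass, fs_hz = sess$frame_hz,
                  lo_hz = lo_hz, hi_hz = hi_hz, order = order))
  sds <- apply(filt, 1, stats::sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  z <- (filt - rowMeans(filt)) / ifelse(sds > 0, sds, 1)
  z[excluded, ] <- 0
  sess$filtered <- filt
  sess$zscored <- z
  sess$excluded <- excluded
  sess$filter_band <- c(lo_hz = lo_hz, hi_hz = hi_hz, order = order)
  sess
}

# Filtered traces if preprocessing has run, otherwise the raw traces.
working_traces <- function(sess) sess$filtered %||% sess$traces

# Z-scored traces, computed on demand if preprocessing has not run.
working_zscores <- function(sess) {
  if (!is.null(sess$zscored)) return(sess$zscored)
  x <- sess$traces
  sds <- apply(x, 1, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  z
}

#' Per-cell event detection threshold
#'
#' The threshold is `2.5 * (sigma_FOV + median_cell)`: `sigma_FOV` is the
#' population standard deviation pooled over every sample of every (filtered)
#' trace in the field of view, and `median_cell` is each cell's median
#' intensity.
#'
#' @param sess a [calcium_session()] (thresholds are computed on `$filtered`
#'   if [preprocess_traces()] has run, else on the raw traces)
#' @param factor multiplier (default 2.5)
#' @return numeric vector of per-cell thresholds, in trace intensity units
#' @export
detection_threshold <- function(sess, factor = 2.5) {
  stopifnot(inherits(sess, "calcium_session"))
  x <- working_traces(sess)
  if (ncol(x) < 2) stop("single-frame traces cannot be thresholded")
  pooled <- as.numeric(x)
  sigma_fov <- sqrt(mean((pooled - mean(pooled))^2))  # population SD
  med_cell <- apply(x, 1, stats::median)
  factor * (sigma_fov + med_cell)
}

#' Detect supra-threshold calcium events
#'
#' Binarizes each cell's (filtered) trace at its threshold; every maximal run
#' of consecutive supra-threshold frames is one event. Onset is the time of
#' the first frame of the run, duration is the run length times the frame
#' interval, and the peak amplitude is the maximum of the z-scored trace
#' within the run.
#'
#' @param sess a [calcium_session()]
#' @param thresholds per-cell thresholds, as from [detection_threshold()]
#' @return data.frame (`EventTable`) with columns `cell_id`, `onset_s`,
#'   `duration_s`, `peak_amplitude`
#' @export
detect_events <- function(sess, thresholds = detection_threshold(sess)) {
  stopifnot(inherits(sess, "calcium_session"),
            length(thresholds) == nrow(sess$traces))
  x <- working_traces(sess)
  z <- working_zscores(sess)
  dt <- 1 / sess$frame_hz
  out <- vector("list", nrow(x))
  for (c_i in seq_len(nrow(x))) {
    if (c_i %in% sess$excluded) next
    above <- x[c_i, ] > thresholds[c_i]
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out[[c_i]] <- data.frame(
      cell_id = sess$centroids$cell_id[c_i],
      onset_s = (starts[keep] - 1L) * dt,
      duration_s = r$lengths[keep] * dt,
      peak_amplitude = vapply(keep, function(k)
        max(z[c_i, starts[k]:ends[k]]), numeric(1)))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(cell_id = integer(), onset_s = numeric(),
                      duration_s = numeric(), peak_amplitude = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cell event summary
#'
#' Event rate (events/min), mean peak amplitude (z-score units) and mean
#' duration (s) per cell. Cells without events get rate 0 and `NA` amplitude
#' and duration.
#'
#' @param events an event table from [detect_events()]
#' @param sess the session the events came from (for duration and cell ids)
#' @return data.frame with columns `cell_id`, `rate_per_min`,
#'   `mean_amplitude`, `mean_duration_s`, `n_events`
#' @export
event_summary <- function(events, sess) {
  total_min <- ncol(sess$traces) / sess$frame_hz / 60
  ids <- sess$centroids$cell_id
  idx <- match(events$cell_id, ids)
  n <- tabulate(idx, nbins = length(ids))
  amp <- rep(NA_real_, length(ids))
  dur <- rep(NA_real_, length(ids))
  if (nrow(events)) {
    amp_s <- tapply(events$peak_amplitude, factor(idx, seq_along(ids)), mean)
    dur_s <- tapply(events$duration_s, factor(idx, seq_along(ids)), mean)
    amp[!is.na(amp_s)] <- amp_s[!is.na(amp_s)]
    dur[!is.na(dur_s)] <- dur_s[!is.na(dur_s)]
  }
  data.frame(cell_id = ids, rate_per_min = n / total_min,
             mean_amplitude = amp, mean_duration_s = dur, n_events = n)
}

#' Sigmoidal amplitude-duration relationship
#'
#' Least-squares fit of the logistic `S(a) = D / (1 + exp(-k (a - a0)))`
#' to per-cell (mean amplitude, mean duration) pairs. `D` is the duration
#' plateau at high amplitude, `k` the slew rate, and `a0` the amplitude at
#' half-maximal duration. The fit is bounded (`D > 0`, `k > 0`) and
#' multi-started from data quantiles to avoid local minima.
#'
#' @param amplitude per-cell mean event amplitudes
#' @param duration_s per-cell mean event durations (s)
#' @return list of class `sigmoid_fit` with `D`, `k`, `a0`, `r2`,
#'   `converged`, `degenerate` and (on failure) `message`
#' @export
fit_amp_duration_sigmoid <- function(amplitude, duration_s) {
  ok <- is.finite(amplitude) & is.finite(duration_s)
  a <- amplitude[ok]
  s <- duration_s[ok]
  if (length(a) < 4)
    stop("at least 4 cells with events are required for the sigmoid fit")
  tss <- sum((s - mean(s))^2)
  if (tss == 0) {  # constant durations: flat fit, exact
    return(structure(list(D = mean(s), k = 0, a0 = NA_real_, r2 = 1,
                          converged = TRUE, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  qs <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  spread <- max(stats::IQR(a), diff(range(a)) / 4, 1e-6)
  starts <- expand.grid(D = c(max(s), 1.5 * max(s)),
                        k = c(1 / spread, 4 / spread),
                        a0 = qs)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ D / (1 + exp(-k * (a - a0))),
        start = as.list(starts[i, ]),
        lower = c(D = 1e-9, k = 1e-9, a0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(D = NA_real_, k = NA_real_, a0 = NA_real_,
                          r2 = NA_real_, converged = FALSE,
                          degenerate = FALSE,
                          message = "all starting points failed to converge"),
                     class = "sigmoid_fit"))
  }
  p <- stats::coef(best$fit)
  structure(list(D = unname(p["D"]), k = unname(p["k"]),
                 a0 = unname(p["a0"]), r2 = 1 - best$rss / tss,
                 converged = TRUE, degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> did not converge:", x$message, "\n")
  } else {
    cat(sprintf("<sigmoid_fit> D = %.4g s, k = %.4g, a0 = %.4g, R2 = %.3f%s\n",
                x$D, x$k, x$a0, x$r2,
                if (x$degenerate) " (degenerate flat fit)" else ""))
  }
  invisible(x)
}

#' Top-hat kernel density map of amplitude vs duration
#'
#' 2-D kernel density estimate over (amplitude, duration) points using a
#' top-hat (uniform disk) kernel of radius `bandwidth` (default 0.75), on a
#' regular grid covering the data plus one bandwidth of padding. Each kernel
#' contributes `1 / (n * pi * h^2)` inside its disk, so the map integrates
#' to 1.
#'
#' @param amplitude,duration_s coordinates of the points
#' @param bandwidth kernel radius (default 0.75)
#' @param grid_n grid resolution per axis (default 128)
#' @return list of class `kde_map` with `amp`, `dur` (grid axes) and
#'   `density` (matrix, `amp` x `dur`)
#' @export
kde_amp_duration <- function(amplitude, duration_s, bandwidth = 0.75,
                             grid_n = 128) {
  ok <- is.finite(amplitude) & is.finite(duration_s)
  a <- amplitude[ok]
  d <- duration_s[ok]
  stopifnot(length(a) >= 1, bandwidth > 0)
  pad <- 1.05 * bandwidth
  ax <- seq(min(a) - pad, max(a) + pad, length.out = grid_n)
  dx <- seq(min(d) - pad, max(d) + pad, length.out = grid_n)
  norm <- 1 / (length(a) * pi * bandwidth^2)
  dens <- matrix(0, grid_n, grid_n)
  h2 <- bandwidth^2
  for (i in seq_along(a)) {
    inside <- outer((ax - a[i])^2, (dx - d[i])^2, `+`) <= h2
    dens <- dens + inside
  }
  dens <- dens * norm
  structure(list(amp = ax, dur = dx, density = dens,
                 bandwidth = bandwidth, n = length(a)),
            class = "kde_map")
}
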