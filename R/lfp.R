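#' LFP recording container
#'
#' Bundles a single-channel local field potential voltage series with its
#' sampling rate and manually scored behavior intervals (resting vs
#' exploring-sniffing).
#'
#' @param samples numeric voltage series (mV)
#' @param fs_hz sampling rate (samples/s)
#' @param intervals data.frame with columns `state` (one of `"rest"`,
#'   `"sniff"`), `start_s`, `end_s`; intervals must lie inside the recording
#'   and must not overlap
#' @param subject_id subject identifier
#' @param genotype `"WT"` or `"KO"`
#' @return an object of class `lfp_recording`
#' @export
lfp_recording <- function(samples, fs_hz, intervals = NULL,
                          subject_id = "s1", genotype = "WT") {
  stopifnot(is.numeric(samples), fs_hz > 0)
  duration <- length(samples) / fs_hz
  if (is.null(intervals)) {
    intervals <- data.frame(state = character(), start_s = numeric(),
                            end_s = numeric())
  }
  stopifnot(all(c("state", "start_s", "end_s") %in% names(intervals)))
  if (nrow(intervals)) {
    if (!all(intervals$state %in% c("rest", "sniff")))
      stop("interval states must be 'rest' or 'sniff'")
    if (any(intervals$start_s < -1e-9) ||
        any(intervals$end_s > duration + 1e-9))
      stop("intervals must lie within [0, duration]")
    if (any(intervals$end_s < intervals$start_s))
      stop("interval end before start")
    o <- order(intervals$start_s)
    iv <- intervals[o, ]
    if (nrow(iv) > 1 &&
        any(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9))
      stop("intervals overlap")
  }
  structure(list(samples = as.numeric(samples), fs_hz = as.numeric(fs_hz),
                 intervals = intervals, subject_id = subject_id,
                 genotype = genotype),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s (%s): %.1f s at %g Hz, %d behavior intervals\n",
              x$subject_id, x$genotype, length(x$samples) / x$fs_hz,
              x$fs_hz, nrow(x$intervals)))
  invisible(x)
}

#' Canonical olfactory-bulb frequency bands
#'
#' Theta 4-12 Hz, beta 15-30 Hz, low gamma 40-70 Hz, high gamma 70-100 Hz.
#'
#' @return data.frame with columns `band`, `lo_hz`, `hi_hz`
#' @export
default_bands <- function() {
  data.frame(band = c("theta", "beta", "low_gamma", "high_gamma"),
             lo_hz = c(4, 15, 40, 70),
             hi_hz = c(12, 30, 70, 100),
             stringsAsFactors = FALSE)
}

#' Pre-process a raw LFP recording
#'
#' Band-pass filters the raw voltage series 1-150 Hz (zero-phase, 5th-order
#' Butterworth response) and resamples it to 250 Hz. Behavior interval labels,
#' expressed in seconds, are carried over unchanged.
#'
#' @param rec an [lfp_recording()]
#' @param lo_hz,hi_hz pre-filter band edges (default 1 and 150 Hz)
#' @param order filter order (default 5)
#' @param target_fs_hz output sampling rate (default 250 Hz)
#' @return a new `lfp_recording` at `target_fs_hz`
#' @export
preprocess_lfp <- function(rec, lo_hz = 1, hi_hz = 150, order = 5,
                           target_fs_hz = 250) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$fs_hz < 2 * hi_hz)
    stop("sampling rate ", rec$fs_hz, " Hz is below twice the upper filter ",
         "edge (", 2 * hi_hz, " Hz)")
  y <- filter_bandpass(rec$samples, rec$fs_hz, lo_hz, hi_hz, order)
  n_out <- as.integer(round(length(y) * target_fs_hz / rec$fs_hz))
  if (n_out != length(y)) y <- fft_resample(y, n_out)
  lfp_recording(y, target_fs_hz, rec$intervals, rec$subject_id, rec$genotype)
}

#' Band-filter an LFP recording
#'
#' Zero-phase band-pass of the recording's voltage series in one of the
#' analysis bands.
#'
#' @param rec an [lfp_recording()] (normally already pre-processed)
#' @param band either a band name from [default_bands()] or a list/row with
#'   `lo_hz` and `hi_hz`
#' @param order filter order (default 5)
#' @return numeric filtered voltage series
#' @export
band_filter <- function(rec, band, order = 5) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.character(band)) {
    bands <- default_bands()
    i <- match(band, bands$band)
    if (is.na(i)) stop("unknown band '", band, "'")
    band <- bands[i, ]
  }
  filter_bandpass(rec$samples, rec$fs_hz, band$lo_hz, band$hi_hz, order)
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method with a periodic Hann window of
#' `window_s` seconds and `overlap_s` seconds of overlap (defaults 0.5 s and
#' 0.25 s). Each segment is demeaned before windowing. With
#' `spectrogram = TRUE` the per-window PSD matrix and window-center times are
#' returned instead of the average.
#'
#' @param x numeric signal
#' @param fs_hz sampling rate (Hz)
#' @param window_s Hann window length in seconds
#' @param overlap_s overlap between consecutive windows in seconds
#' @param spectrogram return the per-window matrix rather than the average
#' @return for the default, a list with `freq_hz`, `power` (units^2/Hz) and
#'   `n_segments`; for `spectrogram = TRUE` additionally `time_s` and `power`
#'   is a frequency x window matrix
#' @export
welch_psd <- function(x, fs_hz, window_s = 0.5, overlap_s = 0.25,
                      spectrogram = FALSE) {
  nper <- as.integer(round(window_s * fs_hz))
  stopifnot(nper >= 2)
  if (length(x) < nper)
    stop("segment (", length(x), " samples) is shorter than one window (",
         nper, " samples)")
  step <- nper - as.integer(round(overlap_s * fs_hz))
  stopifnot(step >= 1)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1L)) / nper)  # periodic Hann
  u <- sum(w^2)
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  nf <- nper %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs_hz / nper
  spec <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs_hz * u)
    p <- p[seq_len(nf)]
    sc <- rep(2, nf)
    sc[1] <- 1
    if (nper %% 2 == 0) sc[nf] <- 1
    spec[, j] <- p * sc
  }
  if (spectrogram) {
    list(freq_hz = freq, power = spec,
         time_s = (starts - 1 + nper / 2) / fs_hz,
         n_segments = length(starts))
  } else {
    list(freq_hz = freq, power = rowMeans(spec), n_segments = length(starts))
  }
}

#' State-conditioned band power
#'
#' For each behavioral state, gathers that state's intervals (in temporal
#' order, capped at `max_total_s` of aggregate data), trims filter-transient
#' edges, computes the Welch PSD per interval, averages the PSDs across
#' intervals weighted by interval length, and then averages power within each
#' band's frequency range. Per (subject, band), powers are additionally
#' normalized by the mean of the rest and sniff values, so the two normalized
#' state powers always average to 1.
#'
#' @param rec a pre-processed [lfp_recording()] with both states present in
#'   its intervals
#' @param bands data.frame as from [default_bands()]
#' @param window_s,overlap_s Welch parameters (defaults 0.5 s and 0.25 s)
#' @param max_total_s aggregation cap per state in seconds (default 900,
#'   i.e. 15 min)
#' @param edge_trim_s seconds trimmed from each end of each interval before
#'   the PSD (default 2; reduced automatically for intervals too short to
#'   retain one Welch window)
#' @return data.frame with columns `subject_id`, `genotype`, `band`, `state`,
#'   `mean_power`, `normalized_power`; states with zero usable time get `NA`
#' @export
state_band_power <- function(rec, bands = default_bands(), window_s = 0.5,
                             overlap_s = 0.25, max_total_s = 900,
                             edge_trim_s = 2) {
  stopifnot(inherits(rec, "lfp_recording"))
  states <- c("rest", "sniff")
  if (!all(states %in% rec$intervals$state))
    stop("both 'rest' and 'sniff' intervals are required")
  fs <- rec$fs_hz
  psd_by_state <- lapply(states, function(st) {
    iv <- rec$intervals[rec$intervals$state == st &
                          rec$intervals$end_s > rec$intervals$start_s, ,
                        drop = FALSE]
    if (!nrow(iv)) return(NULL)
    iv <- iv[order(iv$start_s), , drop = FALSE]
    total <- 0
    acc_power <- NULL
    acc_w <- 0
    for (i in seq_len(nrow(iv))) {
      if (total >= max_total_s) break
      len <- iv$end_s[i] - iv$start_s[i]
      len <- min(len, max_total_s - total)
      trim <- if (len >= 2 * edge_trim_s + window_s) edge_trim_s else
        max(0, (len - window_s) / 2)
      a <- as.integer(round((iv$start_s[i] + trim) * fs)) + 1L
      b <- as.integer(round((iv$start_s[i] + len - trim) * fs))
      if (b - a + 1L < round(window_s * fs)) next
      p <- welch_psd(rec$samples[a:b], fs, window_s, overlap_s)
      wgt <- (b - a + 1L) / fs
      acc_power <- if (is.null(acc_power)) p$power * wgt else
        acc_power + p$power * wgt
      acc_w <- acc_w + wgt
      total <- total + len
      freq <- p$freq_hz
    }
    if (acc_w == 0) return(NULL)
    list(freq = freq, power = acc_power / acc_w)
  })
  names(psd_by_state) <- states
  rows <- do.call(rbind, lapply(seq_len(nrow(bands)), function(bi) {
    vals <- vapply(states, function(st) {
      p <- psd_by_state[[st]]
      if (is.null(p)) return(NA_real_)
      # half-open [lo, hi): adjacent bands share an edge (70 Hz), and a
      # closed interval would count the shared bin in both band averages
      sel <- p$freq >= bands$lo_hz[bi] & p$freq < bands$hi_hz[bi]
      mean(p$power[sel])
    }, numeric(1))
    m <- mean(vals)
    data.frame(subject_id = rec$subject_id, genotype = rec$genotype,
               band = bands$band[bi], state = states,
               mean_power = unname(vals),
               normalized_power = if (any(is.na(vals)) || m == 0)
                 NA_real_ else unname(vals) / m,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Sniff/rest band power ratio
#'
#' Ratio of the mean band power during sniffing over resting, per subject and
#' band. Ratios with zero rest power are undefined and flagged.
#'
#' @param tbl a band power table from [state_band_power()] (possibly several
#'   subjects stacked)
#' @return data.frame with columns `subject_id`, `genotype`, `band`, `ratio`,
#'   `defined`
#' @export
sniff_rest_ratio <- function(tbl) {
  key <- interaction(tbl$subject_id, tbl$band, drop = TRUE)
  out <- do.call(rbind, lapply(split(tbl, key), function(d) {
    rest <- d$mean_power[d$state == "rest"]
    sniff <- d$mean_power[d$state == "sniff"]
    ok <- length(rest) == 1 && length(sniff) == 1 &&
      !is.na(rest) && !is.na(sniff) && rest > 0
    data.frame(subject_id = d$subject_id[1], genotype = d$genotype[1],
               band = d$band[1],
               ratio = if (ok) sniff / rest else NA_real_,
               defined = ok, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
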