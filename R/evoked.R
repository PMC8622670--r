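#' GCaMP6s kernel parameters
#'
#' Rise and decay time constants of the GCaMP6s impulse response and the
#' cell response delay used to position stimulus regressors.
#'
#' @param tau_on_s rise time constant (default 0.11 s)
#' @param tau_off_s decay time constant (default 0.52 s)
#' @param response_delay_s delay between stimulus onset and the fluorescence
#'   response (default 5.6 s)
#' @return list of class `gcamp_kernel_params`
#' @export
gcamp_kernel_params <- function(tau_on_s = 0.11, tau_off_s = 0.52,
                                response_delay_s = 5.6) {
  stopifnot(tau_on_s > 0, tau_off_s > tau_on_s, response_delay_s > 0)
  structure(list(tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                 response_delay_s = response_delay_s),
            class = "gcamp_kernel_params")
}

#' Sampled GCaMP6s impulse-response kernel
#'
#' `h(t) = (1 - exp(-t / tau_on)) * exp(-t / tau_off)` for `t >= 0`, sampled
#' at `dt_s`, truncated after the peak once the kernel falls below `1e-4` of
#' its maximum, and normalized to unit peak.
#'
#' @param params a [gcamp_kernel_params()]
#' @param dt_s sampling interval in seconds (e.g. `1/30` at 30 fps)
#' @return list with `t_s` (sample times) and `h` (kernel values, peak 1)
#' @export
gcamp_kernel <- function(params = gcamp_kernel_params(), dt_s) {
  stopifnot(inherits(params, "gcamp_kernel_params"), dt_s > 0)
  # generous horizon: decay to 1e-4 of peak takes < 12 * tau_off
  t <- seq(0, 15 * params$tau_off_s, by = dt_s)
  h <- (1 - exp(-t / params$tau_on_s)) * exp(-t / params$tau_off_s)
  pk <- max(h)
  ipk <- which.max(h)
  below <- which(h < 1e-4 * pk & seq_along(h) > ipk)
  if (length(below)) {
    t <- t[seq_len(below[1])]
    h <- h[seq_len(below[1])]
  }
  list(t_s = t, h = h / pk)
}

#' Analytic kernel peak time
#'
#' The kernel `(1 - exp(-t/tau_on)) exp(-t/tau_off)` peaks at
#' `tau_on * log(1 + tau_off / tau_on)`.
#'
#' @param params a [gcamp_kernel_params()]
#' @return peak time in seconds
#' @export
kernel_peak_time <- function(params = gcamp_kernel_params()) {
  params$tau_on_s * log(1 + params$tau_off_s / params$tau_on_s)
}

#' Build stimulus regressors
#'
#' One regressor per trial: a boxcar of the trial duration placed at
#' `onset_s + response_delay_s`, convolved with the GCaMP6s kernel and
#' normalized to unit peak (so regression coefficients are response peak
#' amplitudes in trace units). Regressors extending past the session are
#' truncated with a warning.
#'
#' @param protocol data.frame with `trial_id`, `stimulus`, `onset_s`,
#'   `duration_s`
#' @param n_frames number of frames in the session
#' @param frame_hz frame rate (frames/s)
#' @param kernel_params a [gcamp_kernel_params()]
#' @return numeric matrix, trials x frames; zero rows/cols if the protocol
#'   is empty
#' @export
build_regressors <- function(protocol, n_frames, frame_hz,
                             kernel_params = gcamp_kernel_params()) {
  if (is.null(protocol) || nrow(protocol) == 0)
    return(matrix(0, 0, n_frames))
  if (any(protocol$onset_s * frame_hz >= n_frames))
    stop("protocol trials start beyond the end of the session")
  k <- gcamp_kernel(kernel_params, 1 / frame_hz)
  reg <- matrix(0, nrow(protocol), n_frames)
  truncated <- FALSE
  for (i in seq_len(nrow(protocol))) {
    start <- as.integer(round((protocol$onset_s[i] +
                                 kernel_params$response_delay_s) * frame_hz))
    len <- max(1L, as.integer(round(protocol$duration_s[i] * frame_hz)))
    box <- numeric(n_frames)
    idx <- (start + 1L):(start + len)
    if (any(idx > n_frames)) truncated <- TRUE
    idx <- idx[idx >= 1L & idx <= n_frames]
    if (!length(idx)) {
      truncated <- TRUE
    } else {
      box[idx] <- 1
    }
    r <- conv_causal(box, k$h)
    r[abs(r) < 1e-10] <- 0   # FFT convolution residue; regressors are zero
    if (max(r) > 0) r <- r / max(r)   # outside the response window
    reg[i, ] <- r
  }
  if (truncated)
    warning("one or more delayed stimulus windows extend past the session; ",
            "regressors truncated")
  rownames(reg) <- protocol$trial_id
  reg
}

#' Fit odor-evoked response amplitudes
#'
#' Ordinary least squares of each cell's z-scored trace on all trial
#' regressors plus an intercept. Each coefficient is the peak amplitude (in
#' z-score units) of that cell's response to that trial. A trial is flagged
#' responsive when its coefficient exceeds `kappa` standard errors (default
#' `kappa = 3`, calibrated so the per-trial false-positive rate on white
#' noise is below 1%). The effective duration of a responsive trial is the
#' time the trace stays above half the fitted peak within the trial window
#' (from response onset to the next trial's response onset).
#'
#' @param sess a [calcium_session()]; `$zscored` is used if
#'   [preprocess_traces()] has run, otherwise the raw traces
#' @param regressors matrix from [build_regressors()]
#' @param kappa responsiveness criterion in coefficient standard errors
#' @param kernel_params kernel parameters (for the response delay, used to
#'   place trial windows)
#' @return list of class `response_fit` with matrices `coefficients`, `se`,
#'   `responsive`, `effective_duration_s` (cells x trials) and vector
#'   `intercept`
#' @export
fit_responses <- function(sess, regressors, kappa = 3,
                          kernel_params = gcamp_kernel_params()) {
  stopifnot(inherits(sess, "calcium_session"),
            ncol(regressors) == ncol(sess$traces))
  y <- sess$zscored %||% sess$traces
  if (!is.null(sess$filter_band)) {
    # apply the traces' band-pass to the design matrix too, so the model
    # matches the data; re-normalize to unit peak to keep coefficients
    # interpretable as peak amplitudes
    fb <- sess$filter_band
    regressors <- t(apply(rbind(regressors), 1, function(r) {
      rf <- filter_bandpass(r, sess$frame_hz, fb[["lo_hz"]], fb[["hi_hz"]],
                            fb[["order"]])
      if (max(rf) > 0) rf / max(rf) else rf
    }))
    if (nrow(regressors) == 0) regressors <- matrix(0, 0, ncol(y))
  }
  n_tr <- nrow(regressors)
  n_cells <- nrow(y)
  n <- ncol(y)
  x <- cbind(intercept = 1, t(regressors))
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    stop("regressor matrix is rank deficient (overlapping trials?)")
  xtxi <- chol2inv(qr.R(qrx))
  bhat <- qr.coef(qrx, t(y))               # (n_tr + 1) x n_cells
  resid <- t(y) - x %*% bhat
  # Coefficient standard errors from a Newey-West sandwich: band-pass
  # filtered traces have strongly autocorrelated residuals, and the plain
  # OLS variance would understate the error severalfold.
  lag_max <- min(n - 1L, as.integer(round(2 * sess$frame_hz)))
  wts <- 1 - (0:lag_max) / (lag_max + 1)   # Bartlett taper
  cross <- vector("list", lag_max + 1L)
  cross[[1]] <- crossprod(x)
  for (k in seq_len(lag_max)) {
    ck <- crossprod(x[1:(n - k), , drop = FALSE],
                    x[(k + 1):n, , drop = FALSE])
    cross[[k + 1]] <- ck + t(ck)
  }
  se <- matrix(0, ncol(x), n_cells)
  for (ci in seq_len(n_cells)) {
    r <- resid[, ci]
    gam <- vapply(0:lag_max, function(k)
      sum(r[1:(n - k)] * r[(k + 1):n]) / n, numeric(1))
    meat <- Reduce(`+`, Map(function(w, g, cc) w * g * cc,
                            wts, gam, cross))
    v <- xtxi %*% meat %*% xtxi
    se[, ci] <- sqrt(pmax(diag(v), 0))
  }
  coefs <- t(bhat[-1, , drop = FALSE])
  ses <- t(se[-1, , drop = FALSE])
  responsive <- coefs > kappa * ses
  # trial windows in frames: response onset to next response onset (or end)
  onset_f <- as.integer(round((if (n_tr) {
    on <- if (!is.null(sess$protocol) && nrow(sess$protocol) == n_tr)
      sess$protocol$onset_s else rep(NA_real_, n_tr)
    on
  } else numeric(0)) * sess$frame_hz))
  if (n_tr && anyNA(onset_f)) {
    # fall back to the regressors' support if no protocol is attached
    onset_f <- apply(regressors, 1, function(r) which(r > 0)[1] - 1L)
    delay_f <- 0L
  } else {
    delay_f <- as.integer(round(kernel_params$response_delay_s *
                                  sess$frame_hz))
  }
  win_start <- onset_f + delay_f + 1L
  win_end <- c(win_start[-1] - 1L, n)[seq_len(n_tr)]
  eff <- matrix(NA_real_, n_cells, n_tr)
  for (tr in seq_len(n_tr)) {
    a <- min(max(win_start[tr], 1L), n)
    b <- min(max(win_end[tr], a), n)
    seg <- y[, a:b, drop = FALSE]
    for (ci in seq_len(n_cells)) {
      if (coefs[ci, tr] <= 0) next
      above <- seg[ci, ] >= coefs[ci, tr] / 2
      if (!any(above)) {
        eff[ci, tr] <- 0
        next
      }
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ipk <- which.max(seg[ci, ])
      hit <- which(r$values & starts <= ipk & ends >= ipk)
      len <- if (length(hit)) r$lengths[hit[1]] else
        max(r$lengths[r$values])
      eff[ci, tr] <- len / sess$frame_hz
    }
  }
  dimnames(coefs) <- dimnames(ses) <- dimnames(responsive) <-
    dimnames(eff) <- list(sess$centroids$cell_id, rownames(regressors))
  structure(list(coefficients = coefs, se = ses, responsive = responsive,
                 effective_duration_s = eff,
                 intercept = unname(bhat[1, ]), kappa = kappa,
                 fov_id = sess$fov_id, genotype = sess$genotype),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("<response_fit> %s (%s): %d cells x %d trials, kappa = %g\n",
              x$fov_id, x$genotype, nrow(x$coefficients),
              ncol(x$coefficients), x$kappa))
  invisible(x)
}

#' Classify response reliability
#'
#' Counts, per cell, the odor trials flagged responsive and assigns a
#' reliability class: `"all"` (every odor trial), `"none"` (0), `"one"` (1),
#' `"few"` (2 to n_odor - 1). Returns per-cell classes and per-FOV class
#' fractions (which sum to 1).
#'
#' @param fit a [fit_responses()] result
#' @param protocol the stimulus protocol (to identify odor trials); defaults
#'   to treating every trial as an odor trial
#' @return list with `class` (factor per cell), `n_responsive` (per cell)
#'   and `fractions` (named numeric: all/none/one/few)
#' @export
classify_reliability <- function(fit, protocol = NULL) {
  stopifnot(inherits(fit, "response_fit"))
  odor <- if (is.null(protocol)) seq_len(ncol(fit$responsive)) else
    which(protocol$stimulus == "odor")
  n_odor <- length(odor)
  stopifnot(n_odor >= 1)
  cnt <- rowSums(fit$responsive[, odor, drop = FALSE])
  cls <- ifelse(cnt == n_odor, "all",
                ifelse(cnt == 0, "none",
                       ifelse(cnt == 1, "one", "few")))
  if (n_odor == 1) cls[cnt == 1] <- "all"
  cls <- factor(cls, levels = c("all", "few", "one", "none"))
  frac <- as.numeric(table(cls)) / length(cls)
  names(frac) <- levels(cls)
  list(class = cls, n_responsive = cnt, fractions = frac)
}
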