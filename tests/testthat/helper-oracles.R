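# Independent oracle implementations used by the unit and acceptance tests.
# These deliberately use naive, transparent algorithms so they stay
# independent of the package's own code paths.

# Frame-by-frame scan segmentation of one trace at a fixed threshold.
# Returns the same columns as detect_events() for a single cell.
scan_events_oracle <- function(trace, threshold, zscores, frame_hz,
                               cell_id = 1L) {
  onsets <- integer(0)
  durations <- integer(0)
  peaks <- numeric(0)
  in_event <- FALSE
  start <- 0L
  for (t in seq_along(trace)) {
    if (!in_event && trace[t] > threshold) {
      in_event <- TRUE
      start <- t
    }
    if (in_event && (trace[t] <= threshold || t == length(trace))) {
      last <- if (trace[t] <= threshold) t - 1L else t
      onsets <- c(onsets, start)
      durations <- c(durations, last - start + 1L)
      peaks <- c(peaks, max(zscores[start:last]))
      in_event <- FALSE
    }
  }
  data.frame(cell_id = rep(cell_id, length(onsets)),
             onset_s = (onsets - 1L) / frame_hz,
             duration_s = durations / frame_hz, peak_amplitude = peaks)
}

# Brute-force Ward agglomeration by the Lance-Williams update on squared
# Euclidean distances; returns the cophenetic distance matrix (heights on
# the ward.D2 scale, i.e. sqrt of the updated squared distances).
lw_ward_cophenetic <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  for (m in seq_len(n - 1)) {
    bd <- Inf
    bi <- bj <- NA_integer_
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        a <- active[jj]
        b <- active[ii]
        if (d2[a, b] < bd) {
          bd <- d2[a, b]
          bi <- a
          bj <- b
        }
      }
    }
    h <- sqrt(bd)
    for (a in members[[bi]]) for (b in members[[bj]])
      coph[a, b] <- coph[b, a] <- h
    for (k in setdiff(active, c(bi, bj))) {
      d2[bi, k] <- d2[k, bi] <-
        ((size[bi] + size[k]) * d2[bi, k] +
           (size[bj] + size[k]) * d2[bj, k] - size[k] * bd) /
        (size[bi] + size[bj] + size[k])
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    size[bi] <- size[bi] + size[bj]
    active <- setdiff(active, bj)
  }
  coph
}

# Normal-equations least squares: solve (X'X) b = X'y directly.
normal_equations_oracle <- function(x, y) {
  solve(crossprod(x), crossprod(x, y))
}

# A small spontaneous session with uncorrelated cells for detection tests.
make_plain_session <- function(n_cells = 8, n_frames = 300, seed = 1,
                               frame_hz = 30) {
  set.seed(seed)
  traces <- matrix(stats::rnorm(n_cells * n_frames,
                                mean = stats::runif(n_cells, -0.5, 0.5)),
                   n_cells, n_frames)
  calcium_session(traces, frame_hz = frame_hz)
}
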