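#' Parameters for synthetic LFP generation
#'
#' @param duration_s total recording duration (s)
#' @param fs_hz sampling rate (default 10000 samples/s)
#' @param band_amplitudes named list `list(rest = c(theta=, beta=,
#'   low_gamma=, high_gamma=), sniff = ...)` of per-state band amplitudes
#'   (standard deviation of each band-limited component, in mV)
#' @param state_schedule data.frame with columns `state` (`"rest"`/`"sniff"`)
#'   and `duration_s`, in temporal order; total must not exceed `duration_s`
#' @param noise_sd broadband white-noise SD (mV)
#' @param seed integer RNG seed
#' @return list of class `synth_lfp_params`
#' @export
synth_lfp_params <- function(duration_s, fs_hz = 10000,
                             band_amplitudes = list(
                               rest = c(theta = 1, beta = 1,
                                        low_gamma = 1, high_gamma = 1),
                               sniff = c(theta = 1, beta = 1,
                                         low_gamma = 1, high_gamma = 1)),
                             state_schedule = data.frame(
                               state = c("rest", "sniff"),
                               duration_s = duration_s / 2),
                             noise_sd = 0.1, seed = 1) {
  stopifnot(duration_s > 0, fs_hz > 200,
            all(c("rest", "sniff") %in% names(band_amplitudes)),
            all(state_schedule$state %in% c("rest", "sniff")),
            all(state_schedule$duration_s > 0))
  for (st in c("rest", "sniff"))
    stopifnot(all(default_bands()$band %in% names(band_amplitudes[[st]])))
  if (sum(state_schedule$duration_s) > duration_s + 1e-9)
    stop("state schedule is longer than the recording duration")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 band_amplitudes = band_amplitudes,
                 state_schedule = state_schedule,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_lfp_params")
}

#' Generate a synthetic LFP recording
#'
#' Builds the voltage series as a sum over the four analysis bands of
#' band-limited noise (white noise band-passed with the same zero-phase
#' Butterworth response used by the analysis, scaled to unit SD) multiplied
#' by the state-appropriate amplitude from the schedule, plus broadband white
#' noise. Band noise is synthesized at 250 Hz (where all band filters are
#' well conditioned) and spectrally up-sampled to `fs_hz` — exact for the
#' sub-125 Hz content involved. The state schedule is returned as the
#' ground-truth behavior intervals. Identical seeds give identical output.
#'
#' @param params a [synth_lfp_params()]
#' @param subject_id,genotype metadata for the resulting recording
#' @return an [lfp_recording()]
#' @export
gen_lfp <- function(params, subject_id = "synth1", genotype = "WT") {
  stopifnot(inherits(params, "synth_lfp_params"))
  bands <- default_bands()
  fs_in <- 250
  n_in <- as.integer(round(params$duration_s * fs_in))
  n_out <- as.integer(round(params$duration_s * params$fs_hz))
  sched <- params$state_schedule
  edges_s <- cumsum(c(0, sched$duration_s))
  # per-sample state amplitude envelope at the synthesis rate
  t_in <- (seq_len(n_in) - 0.5) / fs_in
  seg <- findInterval(t_in, edges_s, rightmost.closed = TRUE)
  state_of <- ifelse(seg >= 1 & seg <= nrow(sched),
                     as.character(sched$state[pmin(seg, nrow(sched))]), NA)
  x_in <- with_seed(params$seed, {
    acc <- numeric(n_in)
    for (bi in seq_len(nrow(bands))) {
      w <- stats::rnorm(n_in)
      bl <- filter_bandpass(w, fs_in, bands$lo_hz[bi], bands$hi_hz[bi])
      bl <- bl / stats::sd(bl)
      amp <- numeric(n_in)
      for (st in c("rest", "sniff")) {
        amp[which(state_of == st)] <-
          params$band_amplitudes[[st]][[bands$band[bi]]]
      }
      acc <- acc + amp * bl
    }
    noise <- if (params$noise_sd > 0)
      stats::rnorm(n_out, sd = params$noise_sd) else numeric(n_out)
    list(acc = acc, noise = noise)
  })
  x <- if (n_out != n_in) fft_resample(x_in$acc, n_out) else x_in$acc
  x <- x + x_in$noise
  intervals <- data.frame(state = as.character(sched$state),
                          start_s = edges_s[-length(edges_s)],
                          end_s = edges_s[-1],
                          stringsAsFactors = FALSE)
  lfp_recording(x, params$fs_hz, intervals, subject_id, genotype)
}

#' Parameters for synthetic calcium sessions
#'
#' Defaults emulate the study's acquisition and the reported spontaneous
#' statistics: 30 fps, 512 x 512 px FOV, 5 min sessions, event rate around
#' 1.8 per minute.
#'
#' @param n_cells number of cells (>= 1)
#' @param fov_px FOV side in pixels (default 512)
#' @param um_per_px spatial calibration (default 1 um/px)
#' @param frame_hz frame rate (default 30)
#' @param duration_s session length (default 300 s)
#' @param event_rate_per_min spontaneous event rate per cell (default 1.8)
#' @param event_amp_mean,event_amp_sd event amplitude distribution
#'   (truncated-normal at 0; defaults 1.2 and 0.4 dF units)
#' @param corr_length_um spatial correlation decay length lambda; 0 disables
#'   spatial mixing, `Inf` makes all cells share one source (default 100)
#' @param kernel a [gcamp_kernel_params()]
#' @param noise_sd white measurement noise SD (default 0.3)
#' @param drift_amp slow sinusoidal drift amplitude (default 0.1)
#' @param seed integer RNG seed
#' @return list of class `synth_calcium_params`
#' @export
synth_calcium_params <- function(n_cells, fov_px = 512, um_per_px = 1,
                                 frame_hz = 30, duration_s = 300,
                                 event_rate_per_min = 1.8,
                                 event_amp_mean = 1.2, event_amp_sd = 0.4,
                                 corr_length_um = 100,
                                 kernel = gcamp_kernel_params(),
                                 noise_sd = 0.3, drift_amp = 0.1,
                                 seed = 1) {
  stopifnot(n_cells >= 1, fov_px > 0, um_per_px > 0, frame_hz > 0,
            duration_s > 0, event_rate_per_min >= 0,
            corr_length_um >= 0)
  structure(list(n_cells = n_cells, fov_px = fov_px, um_per_px = um_per_px,
                 frame_hz = frame_hz, duration_s = duration_s,
                 event_rate_per_min = event_rate_per_min,
                 event_amp_mean = event_amp_mean,
                 event_amp_sd = event_amp_sd,
                 corr_length_um = corr_length_um, kernel = kernel,
                 noise_sd = noise_sd, drift_amp = drift_amp, seed = seed),
            class = "synth_calcium_params")
}

#' Parameters for synthetic stimulus protocols
#'
#' @param n_odor_trials number of odor-mixture trials (default 7)
#' @param n_oil_trials number of mineral-oil control trials (default 3)
#' @param stim_duration_s stimulus duration (default 2 s)
#' @param inter_trial_s clean-airflow gap between trials (default 40 s,
#'   which keeps the response duty cycle low enough that z-scored evoked
#'   amplitudes are not compressed by the responses' own contribution to
#'   the trace variance)
#' @param responder_fraction fraction of cells that respond to odor (default
#'   0.8)
#' @param response_amp_mean,response_amp_sd evoked amplitude distribution
#'   (truncated-normal at 0; defaults 4 and 1 dF units)
#' @param reliability per-trial probability that a responder responds
#'   (default 0.9)
#' @param seed integer RNG seed (for the trial order)
#' @return list of class `synth_protocol_params`
#' @export
synth_protocol_params <- function(n_odor_trials = 7, n_oil_trials = 3,
                                  stim_duration_s = 2, inter_trial_s = 40,
                                  responder_fraction = 0.8,
                                  response_amp_mean = 4,
                                  response_amp_sd = 1,
                                  reliability = 0.9, seed = 1) {
  stopifnot(n_odor_trials + n_oil_trials >= 1, stim_duration_s > 0,
            inter_trial_s >= 0, responder_fraction >= 0,
            responder_fraction <= 1, reliability >= 0, reliability <= 1)
  structure(list(n_odor_trials = n_odor_trials, n_oil_trials = n_oil_trials,
                 stim_duration_s = stim_duration_s,
                 inter_trial_s = inter_trial_s,
                 responder_fraction = responder_fraction,
                 response_amp_mean = response_amp_mean,
                 response_amp_sd = response_amp_sd,
                 reliability = reliability, seed = seed),
            class = "synth_protocol_params")
}

# Normal draws truncated at 0 (fluorescence transients are non-negative).
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
    guard <- guard + 1L
  }
  if (length(bad)) x[bad] <- .Machine$double.eps
  x
}

#' Generate a pseudo-random stimulus protocol
#'
#' Shuffles `n_odor_trials` odor and `n_oil_trials` oil presentations into a
#' pseudo-random order, spaced by `inter_trial_s`, starting after one
#' inter-trial gap.
#'
#' @param params a [synth_protocol_params()]
#' @param session_duration_s total session length the trials must fit in
#' @return data.frame with `trial_id`, `stimulus`, `onset_s`, `duration_s`
#' @export
gen_protocol <- function(params, session_duration_s) {
  stopifnot(inherits(params, "synth_protocol_params"))
  n <- params$n_odor_trials + params$n_oil_trials
  stim <- with_seed(params$seed,
                    sample(c(rep("odor", params$n_odor_trials),
                             rep("oil", params$n_oil_trials))))
  onsets <- params$inter_trial_s +
    (seq_len(n) - 1) * (params$stim_duration_s + params$inter_trial_s)
  if (max(onsets) + params$stim_duration_s > session_duration_s)
    stop("protocol trials do not fit inside the session duration")
  data.frame(trial_id = seq_len(n), stimulus = stim, onset_s = onsets,
             duration_s = params$stim_duration_s, stringsAsFactors = FALSE)
}

#' Generate a synthetic calcium session with ground truth
#'
#' Cells are placed uniformly in the FOV. Each cell gets a Poisson train of
#' spontaneous events (amplitudes truncated-normal at 0) convolved with the
#' GCaMP6s kernel. Distance-dependent correlation is imposed by mixing the
#' per-cell source signals with the Cholesky factor of the covariance
#' `C_ij = exp(-d_ij / lambda)` (sources standardized before mixing and
#' rescaled afterwards, so pairwise correlations realize `exp(-d/lambda)`);
#' with `corr_length_um = 0` the sources are used unmixed, and with
#' `corr_length_um = Inf` all cells share one source. If a protocol is
#' supplied, a random `responder_fraction` of cells additionally responds at
#' odor-trial onsets with probability `reliability` and truncated-normal
#' amplitude, via the same delayed-boxcar/kernel regressor model used by the
#' analysis; oil trials evoke nothing. Slow sinusoidal drift (period 100 s,
#' random phase per cell) and white noise are added last.
#'
#' @param params a [synth_calcium_params()]
#' @param protocol_params optional [synth_protocol_params()]
#' @param genotype,fov_id metadata for the session
#' @return list with `session` (a [calcium_session()]) and `truth` (list:
#'   `events` data.frame of per-cell source events, `centroids`,
#'   `response_amp` cells x trials matrix or NULL, `responders`, `protocol`)
#' @export
gen_calcium_session <- function(params, protocol_params = NULL,
                                genotype = "WT", fov_id = "synth_fov") {
  stopifnot(inherits(params, "synth_calcium_params"))
  n <- params$n_cells
  n_frames <- as.integer(round(params$duration_s * params$frame_hz))
  fov_um <- params$fov_px * params$um_per_px
  kern <- gcamp_kernel(params$kernel, 1 / params$frame_hz)
  protocol <- if (!is.null(protocol_params))
    gen_protocol(protocol_params, params$duration_s) else NULL

  res <- with_seed(params$seed, {
    centroids <- data.frame(cell_id = seq_len(n),
                            x_um = stats::runif(n, 0, fov_um),
                            y_um = stats::runif(n, 0, fov_um))
    exp_ev <- params$event_rate_per_min * params$duration_s / 60
    ev_list <- lapply(seq_len(n), function(ci) {
      k <- stats::rpois(1, exp_ev)
      if (k == 0)
        return(data.frame(cell_id = integer(), time_s = numeric(),
                          amplitude = numeric()))
      data.frame(cell_id = ci,
                 time_s = sort(stats::runif(k, 0, params$duration_s)),
                 amplitude = rnorm_trunc0(k, params$event_amp_mean,
                                          params$event_amp_sd))
    })
    src <- matrix(0, n, n_frames)
    for (ci in seq_len(n)) {
      ev <- ev_list[[ci]]
      if (nrow(ev)) {
        imp <- numeric(n_frames)
        fr <- pmin(n_frames, as.integer(floor(ev$time_s *
                                                params$frame_hz)) + 1L)
        for (j in seq_along(fr)) imp[fr[j]] <- imp[fr[j]] + ev$amplitude[j]
        src[ci, ] <- conv_causal(imp, kern$h)
      }
    }
    lambda <- params$corr_length_um
    traces <- if (n == 1 || lambda == 0) {
      src
    } else if (is.infinite(lambda)) {
      matrix(rep(src[1, ], each = n), n, n_frames, byrow = FALSE)
    } else {
      d <- as.matrix(stats::dist(centroids[, c("x_um", "y_um")]))
      cmat <- exp(-d / lambda)
      l <- t(chol(cmat + diag(1e-9, n)))
      sds <- apply(src, 1, stats::sd)
      scale <- mean(sds[sds > 0])
      if (!is.finite(scale) || scale == 0) scale <- 1
      zsrc <- (src - rowMeans(src)) / ifelse(sds > 0, sds, 1)
      (l %*% zsrc) * scale
    }
    response_amp <- NULL
    responders <- integer(0)
    if (!is.null(protocol)) {
      n_resp <- round(protocol_params$responder_fraction * n)
      responders <- sort(sample(n, n_resp))
      reg <- build_regressors(protocol, n_frames, params$frame_hz,
                              params$kernel)
      response_amp <- matrix(0, n, nrow(protocol))
      odor <- which(protocol$stimulus == "odor")
      for (ci in responders) {
        for (tr in odor) {
          if (stats::runif(1) < protocol_params$reliability) {
            response_amp[ci, tr] <-
              rnorm_trunc0(1, protocol_params$response_amp_mean,
                           protocol_params$response_amp_sd)
          }
        }
      }
      traces <- traces + response_amp %*% reg
    }
    if (params$drift_amp > 0) {
      tt <- (seq_len(n_frames) - 1) / params$frame_hz
      ph <- stats::runif(n, 0, 2 * pi)
      traces <- traces + params$drift_amp *
        sin(outer(ph, 2 * pi * tt / 100, `+`))
    }
    if (params$noise_sd > 0)
      traces <- traces + matrix(stats::rnorm(n * n_frames,
                                             sd = params$noise_sd),
                                n, n_frames)
    list(traces = traces, centroids = centroids,
         events = do.call(rbind, ev_list), response_amp = response_amp,
         responders = responders)
  })

  sess <- calcium_session(res$traces, res$centroids, params$frame_hz,
                          genotype, fov_id, protocol)
  list(session = sess,
       truth = list(events = res$events, centroids = res$centroids,
                    response_amp = res$response_amp,
                    responders = res$responders, protocol = protocol))
}

#' Parameters for synthetic habituation-dishabituation cohorts
#'
#' Defaults approximate the reported wild-type investigation times
#' (first-trial baseline near 2.8 s, strong habituation, clear
#' dishabituation rebound).
#'
#' @param n_mice number of mice
#' @param habituation_decay multiplicative factor per habituation trial, in
#'   (0, 1] (default 0.55)
#' @param dishabituation_gain relative increase on trial 4 (default 1.8)
#' @param base_time_s first-trial investigation time (default 2.8 s)
#' @param noise_sd_s additive trial noise SD (default 0.5 s)
#' @param seed integer RNG seed
#' @return list of class `synth_behavior_params`
#' @export
synth_behavior_params <- function(n_mice, habituation_decay = 0.55,
                                  dishabituation_gain = 1.8,
                                  base_time_s = 2.8, noise_sd_s = 0.5,
                                  seed = 1) {
  stopifnot(n_mice >= 1, habituation_decay > 0, habituation_decay <= 1,
            dishabituation_gain >= 0, base_time_s >= 0, noise_sd_s >= 0)
  structure(list(n_mice = n_mice, habituation_decay = habituation_decay,
                 dishabituation_gain = dishabituation_gain,
                 base_time_s = base_time_s, noise_sd_s = noise_sd_s,
                 seed = seed),
            class = "synth_behavior_params")
}

#' Generate synthetic habituation-dishabituation trials
#'
#' Per mouse: `t1 = base`, `t_k = t_{k-1} * decay + noise` for trials 2 and
#' 3, and `t4 = t3 * (1 + gain) + noise`; times are clipped at 0.
#'
#' @param params a [synth_behavior_params()]
#' @param genotype genotype label for the cohort
#' @param id_prefix prefix for mouse identifiers
#' @return data.frame with `mouse_id`, `genotype`, `trial`, `time_s`
#' @export
gen_behavior_trials <- function(params, genotype = "WT",
                                id_prefix = genotype) {
  stopifnot(inherits(params, "synth_behavior_params"))
  with_seed(params$seed, {
    rows <- lapply(seq_len(params$n_mice), function(m) {
      t1 <- params$base_time_s
      t2 <- t1 * params$habituation_decay +
        stats::rnorm(1, sd = params$noise_sd_s)
      t3 <- max(0, t2) * params$habituation_decay +
        stats::rnorm(1, sd = params$noise_sd_s)
      t4 <- max(0, t3) * (1 + params$dishabituation_gain) +
        stats::rnorm(1, sd = params$noise_sd_s)
      data.frame(mouse_id = sprintf("%s_%02d", id_prefix, m),
                 genotype = genotype, trial = 1:4,
                 time_s = pmax(0, c(t1, t2, t3, t4)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
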