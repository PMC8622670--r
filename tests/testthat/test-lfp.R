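test_that("preprocessing preserves in-band content and rejects invalid rates", {
  fs <- 2000
  t <- (0:(fs * 20 - 1)) / fs
  rec <- lfp_recording(sin(2 * pi * 60 * t), fs)
  out <- preprocess_lfp(rec)
  expect_equal(out$fs_hz, 250)
  expect_equal(length(out$samples), round(length(t) * 250 / fs))
  core <- out$samples[(2 * 250):(18 * 250)]
  expect_gt(max(abs(core)), 0.95)
  expect_lt(max(abs(core)), 1.05)

  # sub-hertz drift is strongly attenuated (>= 20 dB by design)
  expect_lt(butter_bandpass_gain(0.2, 1, 150), 0.1)
  drift <- lfp_recording(sin(2 * pi * 0.2 * t), fs)
  dcore <- preprocess_lfp(drift)$samples[(2 * 250):(18 * 250)]
  expect_lt(max(abs(dcore)), 0.1)

  expect_error(preprocess_lfp(lfp_recording(rnorm(1000), 250)), "below")
})

test_that("band filtering passes in-band tones and suppresses out-of-band ones", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  core <- (2 * fs):(18 * fs)
  tone50 <- lfp_recording(sin(2 * pi * 50 * t), fs)
  expect_gt(max(abs(band_filter(tone50, "low_gamma")[core])), 0.9)
  expect_lt(max(abs(band_filter(tone50, "theta")[core])), 0.1)
  expect_lt(butter_bandpass_gain(50, 4, 12), 0.01)
  zero <- lfp_recording(numeric(fs * 5), fs)
  expect_lt(max(abs(band_filter(zero, "beta"))), 1e-12)
  expect_error(band_filter(tone50, list(lo_hz = 100, hi_hz = 200)),
               "Nyquist")
})

test_that("Welch PSD localizes tones, satisfies Parseval, and rejects short input", {
  fs <- 250
  t <- (0:(fs * 10 - 1)) / fs
  p <- welch_psd(sin(2 * pi * 20 * t), fs)
  expect_equal(p$freq_hz[which.max(p$power)], 20, tolerance = 1 / 0.5 / 2)

  set.seed(2)
  x <- rnorm(fs * 30, sd = 1.7)
  pw <- welch_psd(x, fs)
  total <- sum(pw$power) * (pw$freq_hz[2] - pw$freq_hz[1])
  expect_equal(total, var(x), tolerance = 0.1)

  expect_true(all(welch_psd(numeric(fs), fs)$power == 0))
  expect_error(welch_psd(rnorm(50), fs), "shorter than one window")

  sg <- welch_psd(x, fs, spectrogram = TRUE)
  expect_true(is.matrix(sg$power))
  expect_equal(nrow(sg$power), length(sg$freq_hz))
  expect_equal(ncol(sg$power), length(sg$time_s))
  expect_equal(rowMeans(sg$power), pw$power)
})

test_that("Welch band power agrees with the band-filtered signal variance", {
  sched <- data.frame(state = c("rest", "sniff"), duration_s = c(32, 32))
  p <- synth_lfp_params(64, fs_hz = 1000, state_schedule = sched,
                        noise_sd = 0.05, seed = 9)
  rec <- preprocess_lfp(gen_lfp(p))
  psd <- welch_psd(rec$samples, rec$fs_hz)
  bands <- default_bands()
  for (bi in seq_len(nrow(bands))) {
    sel <- psd$freq_hz >= bands$lo_hz[bi] & psd$freq_hz < bands$hi_hz[bi]
    welch_power <- mean(psd$power[sel]) * (bands$hi_hz[bi] - bands$lo_hz[bi])
    bf_var <- var(band_filter(rec, bands$band[bi]))
    expect_equal(welch_power, bf_var, tolerance = 0.15)
  }
})

test_that("state band power is normalized per band and ignores degenerate intervals", {
  sched <- data.frame(state = c("rest", "sniff", "rest", "sniff"),
                      duration_s = c(16, 16, 16, 16))
  p <- synth_lfp_params(64, fs_hz = 1000, state_schedule = sched,
                        noise_sd = 0.1, seed = 17)
  rec <- preprocess_lfp(gen_lfp(p))
  tbl <- state_band_power(rec)
  # symmetric amplitudes: both states near 1 after normalization
  expect_true(all(abs(tbl$normalized_power - 1) < 0.15))
  # exact normalization invariant: per band, the two states average to 1
  means <- tapply(tbl$normalized_power, tbl$band, mean)
  expect_true(all(abs(means - 1) < 1e-12))

  # a zero-length interval is ignored without error
  rec2 <- rec
  rec2$intervals <- rbind(rec$intervals,
                          data.frame(state = "rest", start_s = 20,
                                     end_s = 20))
  expect_silent(state_band_power(rec2))

  rec3 <- rec
  rec3$intervals <- rec$intervals[rec$intervals$state == "rest", ]
  expect_error(state_band_power(rec3), "both")
})

test_that("ratios are pure arithmetic and invariant to recording gain", {
  tbl <- data.frame(subject_id = "a", genotype = "WT",
                    band = rep(c("theta", "beta"), each = 2),
                    state = rep(c("rest", "sniff"), 2),
                    mean_power = c(1, 2, 0.5, 0.5),
                    normalized_power = NA)
  r <- sniff_rest_ratio(tbl)
  expect_equal(r$ratio[r$band == "theta"], 2)
  expect_equal(r$ratio[r$band == "beta"], 1)

  tbl$mean_power[tbl$band == "beta" & tbl$state == "rest"] <- 0
  r0 <- sniff_rest_ratio(tbl)
  expect_false(r0$defined[r0$band == "beta"])
  expect_true(is.na(r0$ratio[r0$band == "beta"]))

  sched <- data.frame(state = c("rest", "sniff"), duration_s = c(20, 20))
  p <- synth_lfp_params(40, fs_hz = 1000, state_schedule = sched,
                        noise_sd = 0.1, seed = 23)
  rec <- preprocess_lfp(gen_lfp(p))
  rec3x <- rec
  rec3x$samples <- 3 * rec$samples
  t1 <- state_band_power(rec)
  t3 <- state_band_power(rec3x)
  expect_equal(sniff_rest_ratio(t3)$ratio, sniff_rest_ratio(t1)$ratio,
               tolerance = 1e-10)
  expect_equal(t3$normalized_power, t1$normalized_power, tolerance = 1e-10)
  expect_equal(t3$mean_power, 9 * t1$mean_power, tolerance = 1e-10)
})

test_that("lfp recordings round-trip through the tabular format", {
  sched <- data.frame(state = c("rest", "sniff"), duration_s = c(2, 2))
  p <- synth_lfp_params(4, fs_hz = 500, state_schedule = sched, seed = 1)
  rec <- gen_lfp(p, subject_id = "m7", genotype = "KO")
  d <- file.path(tempdir(), "lfp_rt")
  write_lfp_recording(rec, d)
  back <- read_lfp_recording(d)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$genotype, "KO")
  expect_equal(back$intervals$state, rec$intervals$state)
  unlink(d, recursive = TRUE)
})

test_that("frequency-domain filtering matches recursive zero-phase filtering where both are stable", {
  # the theta band at 250 Hz is well conditioned for the recursive
  # transfer-function design, so the two implementations must agree
  set.seed(6)
  x <- rnorm(250 * 60)
  want <- signal::filtfilt(signal::butter(5, c(4, 12) / 125, "pass"), x)
  got <- filter_bandpass(x, 250, 4, 12)
  core <- (5 * 250):(55 * 250)
  expect_gt(cor(got[core], want[core]), 0.9999)
  expect_equal(sd(got[core]) / sd(want[core]), 1, tolerance = 0.01)
})
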