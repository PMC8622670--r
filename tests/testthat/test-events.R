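test_that("trace preprocessing passes slow transients and removes fast noise", {
  fs <- 30
  t <- (0:(fs * 300 - 1)) / fs
  core <- (20 * fs):(280 * fs)
  sess <- calcium_session(rbind(sin(2 * pi * 0.1 * t),
                                sin(2 * pi * 5 * t)), frame_hz = fs)
  out <- preprocess_traces(sess)
  expect_gt(max(abs(out$filtered[1, core])), 0.9)
  expect_lt(max(abs(out$filtered[2, core])), 0.1)
  expect_lt(butter_bandpass_gain(5, 0.005, 0.8), 0.01)

  z <- out$zscored
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(z, 1, sd), c(1, 1), tolerance = 1e-10)
})

test_that("constant traces are flagged and excluded from detection", {
  sess <- calcium_session(rbind(rep(2, 100), rnorm(100)), frame_hz = 30)
  sess$filtered <- sess$traces  # bypass filtering to keep the constant row
  sess$zscored <- sess$traces
  sess$excluded <- 1L
  ev <- detect_events(sess, thresholds = c(-1, 100))
  expect_false(1 %in% ev$cell_id)  # constant cell skipped despite low threshold
})

test_that("detection threshold follows 2.5 x (pooled sd + cell median)", {
  sess <- calcium_session(rbind(rep(1, 50), rep(3, 50)), frame_hz = 30)
  thr <- detection_threshold(sess)
  expect_identical(thr, c(5, 10))  # pooled population sd of {1,3} is 1

  zero <- calcium_session(matrix(0, 3, 40), frame_hz = 30)
  expect_identical(detection_threshold(zero), c(0, 0, 0))

  # homogeneity: doubling the traces doubles every threshold, exactly
  s1 <- make_plain_session(seed = 10)
  s2 <- s1
  s2$traces <- 2 * s1$traces
  expect_identical(detection_threshold(s2), 2 * detection_threshold(s1))

  # raising one cell's baseline raises that cell's median term; the other
  # cells shift only through the shared sigma_FOV, all by the same amount
  s3 <- s1
  s3$traces[2, ] <- s3$traces[2, ] + 5
  t1 <- detection_threshold(s1)
  t3 <- detection_threshold(s3)
  shared <- (t3 - t1)[-2]
  expect_lt(diff(range(shared)), 1e-10)
  expect_equal(t3[2] - t1[2], shared[1] + 2.5 * 5, tolerance = 1e-10)

  # single-frame traces are rejected at construction
  expect_error(calcium_session(matrix(1, 2, 1), frame_hz = 30))
})

test_that("event segmentation matches a frame-wise scan oracle", {
  # square pulse: 30 supra-threshold frames at 30 fps is one 1.0 s event
  tr <- numeric(200)
  tr[61:90] <- 5
  sess <- calcium_session(rbind(tr, tr * 0), frame_hz = 30)
  ev <- detect_events(sess, thresholds = c(1, 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 1.0)
  expect_equal(ev$onset_s, 2.0)

  below <- detect_events(sess, thresholds = c(100, 100))
  expect_equal(nrow(below), 0)

  # exhaustive agreement with the naive scan on random traces
  for (seed in 1:20) {
    sess <- make_plain_session(n_cells = 10, n_frames = 250, seed = seed)
    thr <- detection_threshold(sess)
    got <- detect_events(sess, thr)
    z <- (sess$traces - rowMeans(sess$traces)) /
      apply(sess$traces, 1, sd)
    want <- do.call(rbind, lapply(1:10, function(ci)
      scan_events_oracle(sess$traces[ci, ], thr[ci], z[ci, ],
                         sess$frame_hz, ci)))
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("noiseless generated events are recovered with matching onsets", {
  p <- synth_calcium_params(n_cells = 5, duration_s = 300,
                            event_rate_per_min = 0.8, corr_length_um = 0,
                            event_amp_mean = 2, event_amp_sd = 0.2,
                            noise_sd = 0, drift_amp = 0, seed = 2)
  g <- gen_calcium_session(p)
  sess <- preprocess_traces(g$session)
  ev <- detect_events(sess)
  truth <- g$truth$events
  expect_equal(nrow(ev), nrow(truth))
  ev <- ev[order(ev$cell_id, ev$onset_s), ]
  truth <- truth[order(truth$cell_id, truth$time_s), ]
  expect_equal(ev$cell_id, truth$cell_id)
  # onsets land within the trace filter's smoothing width of the impulse
  # (the zero-phase 0.8 Hz low-pass edge smears threshold crossings)
  expect_true(all(abs(ev$onset_s - truth$time_s) < 1))
})

test_that("the amplitude-duration sigmoid is recovered and degenerates gracefully", {
  set.seed(7)
  a <- runif(60, -1, 3)
  s <- 2 / (1 + exp(-3 * (a - 1)))
  f <- fit_amp_duration_sigmoid(a, s)
  expect_true(f$converged)
  expect_equal(c(f$D, f$k, f$a0), c(2, 3, 1), tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # the recovered curve is at half its plateau at a0, by construction
  expect_equal(f$D / (1 + exp(-f$k * 0)), f$D / 2)

  flat <- fit_amp_duration_sigmoid(runif(10), rep(1.3, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$D, 1.3)
  expect_equal(flat$r2, 1)

  expect_error(fit_amp_duration_sigmoid(1:3, 1:3), "at least 4")
})

test_that("the top-hat KDE has compact support and unit mass", {
  k1 <- kde_amp_duration(1, 2, bandwidth = 0.75, grid_n = 200)
  da <- k1$amp[2] - k1$amp[1]
  dd <- k1$dur[2] - k1$dur[1]
  expect_equal(sum(k1$density) * da * dd, 1, tolerance = 0.02)
  # zero beyond one bandwidth from the single point
  far <- outer((k1$amp - 1)^2, (k1$dur - 2)^2, `+`) > 0.76^2
  expect_true(all(k1$density[far] == 0))

  k2 <- kde_amp_duration(c(0, 10), c(0, 10), bandwidth = 0.75, grid_n = 400)
  da <- k2$amp[2] - k2$amp[1]
  dd <- k2$dur[2] - k2$dur[1]
  expect_equal(sum(k2$density) * da * dd, 1, tolerance = 0.02)
  near1 <- outer((k2$amp - 0)^2, (k2$dur - 0)^2, `+`) <= 0.75^2
  near2 <- outer((k2$amp - 10)^2, (k2$dur - 10)^2, `+`) <= 0.75^2
  m1 <- sum(k2$density[near1]) * da * dd
  m2 <- sum(k2$density[near2]) * da * dd
  expect_equal(m1, m2, tolerance = 0.05)
  expect_equal(m1 + m2, 1, tolerance = 0.02)
})

test_that("per-cell event summaries report rates in events per minute", {
  tr <- numeric(1800)  # 60 s at 30 fps
  tr[c(101:110, 501:520, 1001:1005)] <- 5
  sess <- calcium_session(rbind(tr, tr * 0), frame_hz = 30)
  ev <- detect_events(sess, thresholds = c(1, 1))
  s <- event_summary(ev, sess)
  expect_equal(s$rate_per_min, c(3, 0))
  expect_equal(s$n_events, c(3L, 0L))
  expect_true(is.na(s$mean_duration_s[2]))
})
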