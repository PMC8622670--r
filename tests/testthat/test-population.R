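test_that("pairwise correlations match the covariance formula and basic identities", {
  set.seed(5)
  tr <- matrix(rnorm(5 * 100), 5, 100)
  sess <- calcium_session(tr, frame_hz = 30)
  cc <- pairwise_correlation(sess)
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_equal(cc, t(cc), ignore_attr = TRUE)
  # hand-rolled covariance / variance computation
  z <- (tr - rowMeans(tr)) / apply(tr, 1, sd)
  for (i in 1:5) for (j in 1:5) {
    xi <- z[i, ] - mean(z[i, ])
    xj <- z[j, ] - mean(z[j, ])
    expect_equal(cc[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }

  neg <- calcium_session(rbind(tr[1, ], -tr[1, ]), frame_hz = 30)
  expect_equal(pairwise_correlation(neg)[1, 2], -1, tolerance = 1e-12)

  cst <- calcium_session(rbind(tr[1, ], rep(2, 100), tr[2, ]), frame_hz = 30)
  cst$zscored <- rbind(tr[1, ], rep(2, 100), tr[2, ])
  cmat <- pairwise_correlation(cst)
  expect_true(is.na(cmat[1, 2]) && is.na(cmat[2, 3]))
  expect_equal(attr(cmat, "n_excluded"), 1L)
})

test_that("distance binning is half-open at 56 um and conserves pair counts", {
  set.seed(8)
  n <- 30
  cent <- data.frame(cell_id = 1:n, x_um = runif(n, 0, 400),
                     y_um = runif(n, 0, 400))
  tr <- matrix(rnorm(n * 200), n, 200)
  sess <- calcium_session(tr, cent, frame_hz = 30)
  prof <- correlation_vs_distance(pairwise_correlation(sess), cent)
  expect_equal(sum(prof$profile$n_pairs), n * (n - 1) / 2)
  expect_true(all(prof$profile$bin_hi_um - prof$profile$bin_lo_um == 56))
  expect_equal(prof$average_r, mean(prof$pair_r))

  same <- data.frame(cell_id = 1:4, x_um = 10, y_um = 10)
  tr4 <- matrix(rnorm(4 * 100), 4, 100)
  s4 <- calcium_session(tr4, same, frame_hz = 30)
  p4 <- correlation_vs_distance(pairwise_correlation(s4), same)
  expect_equal(nrow(p4$profile), 1)
  expect_equal(p4$profile$bin_lo_um, 0)
  expect_equal(p4$profile$bin_hi_um, 56)

  # a pair exactly on a bin edge goes to the upper bin (half-open bins)
  edge <- data.frame(cell_id = 1:2, x_um = c(0, 56), y_um = 0)
  s2 <- calcium_session(matrix(rnorm(200), 2, 100), edge, frame_hz = 30)
  p2 <- correlation_vs_distance(pairwise_correlation(s2), edge)
  expect_equal(p2$profile$bin_lo_um, 56)
})

test_that("spontaneous activity vectors use 1000-frame windows at 30 fps", {
  n <- 30 * 100  # 100 s
  sess <- calcium_session(matrix(rnorm(5 * n), 5, n), frame_hz = 30)
  sess$zscored <- matrix(0.7, 5, n)
  v <- fov_activity_vector(sess, "spontaneous")
  expect_length(v$values, 3)           # 3000 frames -> 3 windows, 0 dropped
  expect_equal(v$values, rep(0.7, 3))

  sess2 <- calcium_session(matrix(rnorm(5 * 3200), 5, 3200), frame_hz = 30)
  expect_length(fov_activity_vector(sess2, "spontaneous")$values, 3)

  short <- calcium_session(matrix(rnorm(5 * 900), 5, 900), frame_hz = 30)
  expect_error(fov_activity_vector(short, "spontaneous"), "shorter")

  fit <- structure(list(coefficients = matrix(1:20, 2, 10),
                        fov_id = "f", genotype = "WT"),
                   class = "response_fit")
  sessp <- calcium_session(matrix(rnorm(5 * 900), 5, 900), frame_hz = 30)
  ve <- fov_activity_vector(sessp, "evoked", fit)
  expect_length(ve$values, 10)
})

test_that("Ward clustering matches the Lance-Williams oracle and handles duplicates", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- sample(5:12, 1)
    x <- matrix(rnorm(m * 4), m, 4)
    vecs <- lapply(seq_len(m), function(i)
      structure(list(fov_id = paste0("f", i),
                     genotype = sample(c("WT", "KO"), 1),
                     mode = "spontaneous", values = x[i, ]),
                class = "fov_activity_vector"))
    res <- ward_cluster(vecs, k = 2)
    got <- stats::cophenetic(res$hclust)
    want <- lw_ward_cophenetic(x)
    expect_equal(as.matrix(got), want, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("well-separated populations are split perfectly with full compositions", {
  set.seed(42)
  mk <- function(mu, genotype, i)
    structure(list(fov_id = paste0(genotype, i), genotype = genotype,
                   mode = "evoked",
                   values = rnorm(10, mu, 0.1)),
              class = "fov_activity_vector")
  vecs <- c(lapply(1:8, function(i) mk(5, "WT", i)),
            lapply(1:8, function(i) mk(2, "KO", i)))
  res <- ward_cluster(vecs, k = 2)
  expect_equal(length(unique(res$labels[1:8])), 1)
  expect_equal(length(unique(res$labels[9:16])), 1)
  expect_true(res$labels[1] != res$labels[9])
  expect_true(all(res$composition$pct_WT + res$composition$pct_KO == 100))

  # duplicated vectors merge first, at zero height
  dupvecs <- c(vecs[c(1, 1)], vecs[9:10])
  res2 <- ward_cluster(dupvecs, k = 2)
  expect_equal(min(res2$hclust$height), 0)
  expect_equal(res2$hclust$merge[1, ], c(-1, -2))

  bad <- c(vecs[1:2], list(structure(list(fov_id = "x", genotype = "WT",
                                          mode = "evoked", values = 1:3),
                                     class = "fov_activity_vector")))
  expect_error(ward_cluster(bad), "unequal")
})

test_that("exponential spatial correlation structure is recovered from traces", {
  p <- synth_calcium_params(n_cells = 100, corr_length_um = 100, seed = 19)
  g <- gen_calcium_session(p)
  sess <- preprocess_traces(g$session)
  prof <- correlation_vs_distance(pairwise_correlation(sess),
                                  sess$centroids)
  dec <- fit_correlation_decay(prof)
  expect_gt(dec$lambda_um, 80)
  expect_lt(dec$lambda_um, 120)
})

test_that("calcium sessions round-trip through the tabular format", {
  pp <- synth_protocol_params(n_odor_trials = 2, n_oil_trials = 1,
                              inter_trial_s = 5, seed = 2)
  p <- synth_calcium_params(n_cells = 3, duration_s = 40, seed = 2)
  g <- gen_calcium_session(p, pp, genotype = "KO", fov_id = "fovX")
  d <- file.path(tempdir(), "ca_rt")
  write_calcium_session(g$session, d)
  back <- read_calcium_session(d)
  expect_equal(back$traces, g$session$traces, tolerance = 1e-10)
  expect_equal(back$centroids$x_um, g$session$centroids$x_um,
               tolerance = 1e-10)
  expect_equal(back$genotype, "KO")
  expect_equal(back$protocol$stimulus, g$session$protocol$stimulus)
  unlink(d, recursive = TRUE)
})
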