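#' Pairwise Pearson correlation between cells
#'
#' Symmetric matrix of Pearson correlation coefficients between all cell
#' pairs. In `"spontaneous"` mode the full z-scored traces are used; in
#' `"evoked"` mode the traces are restricted to the concatenated
#' stimulus-response windows (response onset to the next trial's response
#' onset). Cells with constant traces have undefined correlations; their
#' rows/columns are `NA` and their count is reported in the
#' `"n_excluded"` attribute.
#'
#' @param sess a [calcium_session()] (pre-processed for spontaneous mode)
#' @param mode `"spontaneous"` or `"evoked"`
#' @param kernel_params kernel parameters (for the response delay in evoked
#'   mode)
#' @return correlation matrix with unit diagonal
#' @export
pairwise_correlation <- function(sess, mode = c("spontaneous", "evoked"),
                                 kernel_params = gcamp_kernel_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(sess, "calcium_session"), nrow(sess$traces) >= 2)
  z <- working_zscores(sess)
  if (mode == "evoked") {
    if (is.null(sess$protocol) || !nrow(sess$protocol))
      stop("evoked mode requires a stimulus protocol")
    n <- ncol(z)
    start_f <- as.integer(round((sess$protocol$onset_s +
                                   kernel_params$response_delay_s) *
                                  sess$frame_hz)) + 1L
    end_f <- c(start_f[-1] - 1L, n)
    keep <- unlist(mapply(function(a, b) seq(min(a, n), min(b, n)),
                          start_f, end_f, SIMPLIFY = FALSE))
    z <- z[, unique(keep), drop = FALSE]
  }
  sds <- apply(z, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(z)))
  bad <- which(sds == 0)
  cc[bad, ] <- NA_real_
  cc[, bad] <- NA_real_
  diag(cc) <- 1
  attr(cc, "n_excluded") <- length(bad)
  cc
}

#' Correlation as a function of inter-soma distance
#'
#' Assigns every cell pair to a half-open distance bin `[k*bin_um,
#' (k+1)*bin_um)` by the Euclidean distance between centroids and reports the
#' per-bin mean, SD and pair count of the pairwise correlations, plus the
#' overall mean correlation across all pairs.
#'
#' @param corr correlation matrix from [pairwise_correlation()]
#' @param centroids data.frame with `x_um`, `y_um` (one row per cell)
#' @param bin_um bin width in micrometers (default 56)
#' @return list of class `correlation_profile` with `profile` (data.frame:
#'   `bin_lo_um`, `bin_hi_um`, `mean_r`, `sd_r`, `n_pairs`) and `average_r`
#' @export
correlation_vs_distance <- function(corr, centroids, bin_um = 56) {
  n <- nrow(corr)
  stopifnot(n == nrow(centroids), bin_um > 0)
  iu <- which(upper.tri(corr), arr.ind = TRUE)
  d <- sqrt((centroids$x_um[iu[, 1]] - centroids$x_um[iu[, 2]])^2 +
              (centroids$y_um[iu[, 1]] - centroids$y_um[iu[, 2]])^2)
  r <- corr[iu]
  ok <- !is.na(r)
  bin <- floor(d / bin_um)
  bins <- sort(unique(bin[ok]))
  prof <- do.call(rbind, lapply(bins, function(b) {
    sel <- ok & bin == b
    data.frame(bin_lo_um = b * bin_um, bin_hi_um = (b + 1) * bin_um,
               mean_r = mean(r[sel]),
               sd_r = if (sum(sel) > 1) stats::sd(r[sel]) else NA_real_,
               n_pairs = sum(sel))
  }))
  structure(list(profile = prof, average_r = mean(r[ok]),
                 pair_distance_um = d[ok], pair_r = r[ok]),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %d pairs in %d bins, mean r = %.3f\n",
              sum(x$profile$n_pairs), nrow(x$profile), x$average_r))
  invisible(x)
}

#' Exponential decay length of a correlation profile
#'
#' Fits `r(d) = A * exp(-d / lambda)` to the pair-level correlations of a
#' [correlation_vs_distance()] result by nonlinear least squares, seeded
#' from a log-linear regression on the positive binned means.
#'
#' @param profile a `correlation_profile`
#' @return list with `A` and `lambda_um`
#' @export
fit_correlation_decay <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  d <- profile$pair_distance_um
  r <- profile$pair_r
  pb <- profile$profile[profile$profile$mean_r > 0, ]
  start <- if (nrow(pb) >= 2) {
    mid <- (pb$bin_lo_um + pb$bin_hi_um) / 2
    sl <- stats::coef(stats::lm(log(pb$mean_r) ~ mid, weights = pb$n_pairs))
    list(A = exp(unname(sl[1])), lambda = -1 / min(unname(sl[2]), -1e-6))
  } else list(A = max(r), lambda = max(d) / 3)
  fit <- minpack.lm::nlsLM(r ~ A * exp(-d / lambda), start = start,
                           lower = c(A = 1e-9, lambda = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  list(A = unname(p["A"]), lambda_um = unname(p["lambda"]))
}

#' Field-of-view activity vector
#'
#' In `"spontaneous"` mode: the mean over cells and frames of the z-scored
#' activity within consecutive 33.3 s windows (1000 frames at 30 fps,
#' otherwise `round(33.3 * frame_hz)` frames); a trailing partial window is
#' dropped. In `"evoked"` mode: the mean over cells of the fitted response
#' amplitude for each stimulus trial.
#'
#' @param sess a [calcium_session()]
#' @param mode `"spontaneous"` or `"evoked"`
#' @param fit for evoked mode, a [fit_responses()] result for this session
#' @param period_s spontaneous window length in seconds (default 33.3)
#' @return list of class `fov_activity_vector` with `fov_id`, `genotype`,
#'   `mode` and `values`
#' @export
fov_activity_vector <- function(sess, mode = c("spontaneous", "evoked"),
                                fit = NULL, period_s = 33.3) {
  mode <- match.arg(mode)
  stopifnot(inherits(sess, "calcium_session"))
  if (mode == "spontaneous") {
    win <- if (sess$frame_hz == 30) 1000L else
      as.integer(round(period_s * sess$frame_hz))
    n <- ncol(sess$traces)
    k <- n %/% win
    if (k < 1)
      stop("session shorter than one ", period_s, " s window")
    z <- working_zscores(sess)
    vals <- vapply(seq_len(k), function(j)
      mean(z[, ((j - 1L) * win + 1L):(j * win)]), numeric(1))
  } else {
    if (is.null(fit)) stop("evoked mode requires a response fit")
    vals <- colMeans(fit$coefficients)
  }
  structure(list(fov_id = sess$fov_id, genotype = sess$genotype,
                 mode = mode, values = unname(vals)),
            class = "fov_activity_vector")
}

#' Ward clustering of FOV activity vectors
#'
#' Ward linkage (on Euclidean distances; `hclust` method `"ward.D2"`) over
#' field-of-view activity vectors, cut into `k` flat clusters. Reports, per
#' cluster, the genotype composition in percent, the mean vector amplitude,
#' and (optionally) the mean of a per-FOV correlation summary.
#'
#' @param vectors list of [fov_activity_vector()] objects of equal length
#' @param k number of flat clusters (the spontaneous analysis uses 4, the
#'   evoked analysis 2)
#' @param avg_corr optional per-FOV average correlation coefficients
#' @return list of class `cluster_result` with `hclust`, `labels`,
#'   `composition` (data.frame: cluster, n, pct_WT, pct_KO, mean_amplitude,
#'   mean_correlation)
#' @export
ward_cluster <- function(vectors, k = 2, avg_corr = NULL) {
  stopifnot(length(vectors) >= 2)
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(lens)) != 1)
    stop("activity vectors have unequal lengths")
  x <- do.call(rbind, lapply(vectors, `[[`, "values"))
  rownames(x) <- vapply(vectors, `[[`, "", "fov_id")
  genotype <- vapply(vectors, `[[`, "", "genotype")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = min(k, nrow(x)))
  comp <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    sel <- labels == cl
    data.frame(cluster = cl, n = sum(sel),
               pct_WT = 100 * mean(genotype[sel] == "WT"),
               pct_KO = 100 * mean(genotype[sel] == "KO"),
               mean_amplitude = mean(x[sel, , drop = FALSE]),
               mean_correlation = if (is.null(avg_corr)) NA_real_ else
                 mean(avg_corr[sel]))
  }))
  structure(list(hclust = hc, labels = labels, composition = comp,
                 genotype = genotype),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d FOVs in %d clusters\n",
              length(x$labels), nrow(x$composition)))
  print(x$composition, row.names = FALSE)
  invisible(x)
}
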