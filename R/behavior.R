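#' Habituation summary
#'
#' Per-genotype, per-trial mean and SD of investigation time in the 4-trial
#' habituation-dishabituation task (three water trials, then a novel
#' odorant).
#'
#' @param tbl data.frame with columns `mouse_id`, `genotype`, `trial`
#'   (1 to 4), `time_s`; exactly one row per mouse x trial
#' @return data.frame with `genotype`, `trial`, `n`, `mean_s`, `sd_s`
#' @export
habituation_summary <- function(tbl) {
  stopifnot(all(c("mouse_id", "genotype", "trial", "time_s") %in% names(tbl)))
  per_mouse <- table(tbl$mouse_id)
  trials_per_mouse <- tapply(tbl$trial, tbl$mouse_id,
                             function(tr) length(tr) == 4 &&
                               all(sort(tr) == 1:4))
  if (!all(trials_per_mouse) || any(per_mouse != 4))
    stop("every mouse needs exactly one row for each of trials 1-4")
  out <- do.call(rbind, lapply(split(tbl, tbl$genotype), function(g) {
    do.call(rbind, lapply(1:4, function(tr) {
      v <- g$time_s[g$trial == tr]
      data.frame(genotype = g$genotype[1], trial = tr, n = length(v),
                 mean_s = mean(v),
                 sd_s = if (length(v) > 1) stats::sd(v) else 0)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Dishabituation test
#'
#' Paired two-sided Wilcoxon signed-rank test of trial-4 vs trial-3
#' investigation times, per genotype (exact distribution when the sample
#' permits, i.e. no ties or zeros and n <= 25). A genotype with fewer than 3
#' mice is reported as insufficient; all-zero differences make the test
#' degenerate and are reported as such rather than given a p-value.
#'
#' @param tbl trial table as for [habituation_summary()]
#' @return data.frame with `genotype`, `n`, `statistic`, `p_value`,
#'   `status` (`"ok"`, `"insufficient"` or `"degenerate"`)
#' @export
dishabituation_test <- function(tbl) {
  out <- do.call(rbind, lapply(split(tbl, tbl$genotype), function(g) {
    t3 <- g$time_s[g$trial == 3][order(g$mouse_id[g$trial == 3])]
    t4 <- g$time_s[g$trial == 4][order(g$mouse_id[g$trial == 4])]
    stopifnot(length(t3) == length(t4))
    n <- length(t3)
    if (n < 3) {
      return(data.frame(genotype = g$genotype[1], n = n,
                        statistic = NA_real_, p_value = NA_real_,
                        status = "insufficient", stringsAsFactors = FALSE))
    }
    if (all(t4 - t3 == 0)) {
      return(data.frame(genotype = g$genotype[1], n = n,
                        statistic = NA_real_, p_value = NA_real_,
                        status = "degenerate", stringsAsFactors = FALSE))
    }
    w <- suppressWarnings(stats::wilcox.test(t4, t3, paired = TRUE,
                                             alternative = "two.sided"))
    data.frame(genotype = g$genotype[1], n = n,
               statistic = unname(w$statistic), p_value = w$p.value,
               status = "ok", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
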