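#' Rank-based group comparison
#'
#' Shared wrapper for the rank tests used throughout the analyses:
#' Mann-Whitney U (two independent groups), paired Wilcoxon signed-rank, and
#' Kruskal-Wallis (two or more independent groups). Two-sided p-values;
#' exact small-sample distributions where the data permit (no ties, and for
#' the paired test no zero differences), normal approximation with tie
#' correction otherwise, following the conventions of [stats::wilcox.test()]
#' and [stats::kruskal.test()]. Zero paired differences are dropped (the
#' standard Wilcoxon convention).
#'
#' @param groups list of numeric vectors: exactly 2 for `mann_whitney` and
#'   `wilcoxon_paired` (equal lengths for the latter), 2 or more for
#'   `kruskal_wallis`
#' @param test one of `"mann_whitney"`, `"wilcoxon_paired"`,
#'   `"kruskal_wallis"`
#' @return list of class `group_comparison` with `test`, `statistic`,
#'   `p_value`, `n` (group sizes)
#' @export
compare_groups <- function(groups,
                           test = c("mann_whitney", "wilcoxon_paired",
                                    "kruskal_wallis")) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  res <- switch(
    test,
    mann_whitney = {
      stopifnot(length(groups) == 2)
      suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                          alternative = "two.sided"))
    },
    wilcoxon_paired = {
      stopifnot(length(groups) == 2,
                length(groups[[1]]) == length(groups[[2]]))
      suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                          paired = TRUE,
                                          alternative = "two.sided"))
    },
    kruskal_wallis = stats::kruskal.test(groups))
  structure(list(test = test, statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n = vapply(groups, length, integer(1))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}
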