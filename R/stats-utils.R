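#' Wilcoxon rank-sum / signed-rank test
#'
#' Two-sided Wilcoxon test as used throughout the package's comparisons:
#' unpaired (Mann-Whitney U) for independent groups, paired (signed-rank on
#' non-zero differences) for matched observations such as per-sample mapping
#' rates under two reference annotations. The exact null distribution is
#' enumerated when both groups have at most 8 observations and there are no
#' ties; otherwise the tie-corrected normal approximation is used. A paired
#' test in which every difference is zero is degenerate and returns p = 1
#' with a warning.
#'
#' @param x,y Numeric vectors (equal length when `paired = TRUE`).
#' @param paired Paired signed-rank test instead of rank-sum.
#' @return List with `statistic` (U, or V for paired) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (all(d == 0)) {
      warning("all paired differences are zero; test degenerate, p = 1")
      return(list(statistic = 0, p_value = 1))
    }
    nz <- d[d != 0]
    exact <- length(nz) <= 8 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = exact,
                                              correct = !exact,
                                              alternative = "two.sided"))
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = FALSE,
                                              exact = exact,
                                              correct = !exact,
                                              alternative = "two.sided"))
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Monotone; never decreases a
#' p-value; invariant (up to reordering) under permutation of the input.
#' `NA` entries are preserved and excluded from the number of tests.
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen case
#' receives a higher score than a randomly chosen control, with ties
#' counting one half. Computed from midranks, so it equals the brute-force
#' pair-counting definition exactly.
#'
#' @param prob Numeric scores (higher = more case-like).
#' @param labels Logical or 0/1 vector; `TRUE`/1 = case.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(prob, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(prob, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval on a binomial proportion via beta quantiles.
#' Used for the confidence intervals on sensitivity reported alongside every
#' classifier evaluation.
#'
#' @param successes Number of successes (e.g. true positives).
#' @param n Number of trials (e.g. cases).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(successes >= 0, successes <= n, n > 0)
  a <- (1 - level) / 2
  low <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(low = low, high = high)
}
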