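# The four statistical primitives of the pipeline. Each is a thin wrapper
# around the corresponding base R routine, pinned to the conventions used
# throughout the package:
#   * Fisher: two-sided by the "probability at most observed" rule
#     (fisher.test's convention); a zero margin is uninformative, p = 1.
#   * Wilcoxon: exact enumeration when there are no ties and n1 + n2 <= 12,
#     otherwise normal approximation with tie and continuity correction.
#   * Kendall: tau-b (tie-corrected) with tie-adjusted normal approximation
#     and continuity correction; pairs with missing values dropped.
#   * BH: Benjamini-Hochberg step-up; missing p propagate missing q and do
#     not count toward m.

WILCOXON_EXACT_MAX_N <- 12

test_result <- function(statistic, p_value, method, n_effective) {
  tibble(statistic = as.numeric(statistic), p_value = as.numeric(p_value),
         method = method, n_effective = as.integer(n_effective))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d Cell counts, row-wise: `a` cases methylated, `b` cases
#'   unmethylated, `c` controls methylated, `d` controls unmethylated.
#' @return One-row tibble: statistic (odds ratio estimate), p_value, method,
#'   n_effective. A zero margin gives p = 1.
#' @examples
#' fisher_exact_2x2(4, 0, 0, 4)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts) | counts < 0 | counts != floor(counts))) {
    abort("fisher_exact_2x2: counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("fisher_exact_2x2: table total must be positive")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(test_result(NA_real_, 1, "fisher_exact", sum(counts)))
  }
  ft <- fisher.test(m)
  test_result(unname(ft$estimate), ft$p.value, "fisher_exact", sum(counts))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when both groups are tie-free and `length(x) + length(y) <= 12`;
#' otherwise the normal approximation with tie correction and continuity
#' correction. All observations identical gives p = 1.
#'
#' @param x,y Numeric vectors for the two groups (each non-empty).
#' @return One-row tibble: statistic (W), p_value, method, n_effective.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    abort("wilcoxon_rank_sum: both groups need at least one observation")
  }
  n <- length(x) + length(y)
  if (length(unique(c(x, y))) == 1) {
    return(test_result(length(x) * length(y) / 2, 1, "wilcoxon_degenerate", n))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n <= WILCOXON_EXACT_MAX_N) {
    wt <- wilcox.test(x, y, exact = TRUE)
    method <- "wilcoxon_exact"
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    method <- "wilcoxon_normal"
  }
  test_result(unname(wt$statistic), wt$p.value, method, n)
}

#' Kendall tau-b correlation test
#'
#' Tie-corrected tau-b with two-sided p-value from the tie-adjusted normal
#' approximation with continuity correction. Pairs with a missing value in
#' either vector are dropped; fewer than 3 complete pairs or zero variance
#' in either vector gives a missing statistic and p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: statistic (tau-b), p_value, method, n_effective
#'   (complete pairs used).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) abort("kendall_tau: x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(test_result(NA_real_, 1, "kendall_degenerate", n))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = FALSE, continuity = TRUE))
  test_result(unname(ct$estimate), ct$p.value, "kendall_tau_b", n)
}

# fast path used in per-pair loops: returns c(tau, p)
kendall_tau_fast <- function(x, y) {
  r <- kendall_tau(x, y)
  c(r$statistic, r$p_value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. Missing p-values propagate missing q-values and
#' are not counted in the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("bh_fdr: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
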