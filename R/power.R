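#' Power of a two-sided paired t-test
#'
#' Exact noncentral-t computation: with n pairs and standardized effect size
#' d (mean change in units of the SD of the change), the test statistic under
#' the alternative is noncentral t with n - 1 degrees of freedom and
#' noncentrality d * sqrt(n); power is the probability that it exceeds the
#' two-sided critical value,
#' `P(T' > t_{1-alpha/2, n-1}) + P(T' < -t_{1-alpha/2, n-1})`.
#'
#' @param n number of pairs (>= 2).
#' @param d Cohen's d for paired differences (>= 0).
#' @param alpha two-sided significance level. Note this is the
#'   per-comparison level after any multiplicity adjustment — e.g. 0.025 when
#'   0.05 is split over two primary outcomes.
#' @return Power in [0, 1]. With d = 0 this is the test's size, alpha.
#' @examples
#' pairedTPower(n = 22, d = 0.7, alpha = 0.025)  # ~0.80
#' @export
pairedTPower <- function(n, d, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(alpha > 0, alpha < 1, d >= 0)
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Smallest sample size reaching a target power
#'
#' Increments n from 2 until [pairedTPower()] meets the target; monotone in
#' the target because power is strictly increasing in n.
#'
#' @param target desired power in (0, 1).
#' @param d paired Cohen's d (> 0 unless target <= alpha).
#' @param alpha two-sided per-comparison significance level.
#' @param n_max search ceiling (error if exceeded).
#' @return Integer n with `pairedTPower(n) >= target` and
#'   `pairedTPower(n - 1) < target` (or the floor n = 2).
#' @examples
#' solveSampleSize(0.8, d = 0.7, alpha = 0.025)
#' @export
solveSampleSize <- function(target, d, alpha = 0.05, n_max = 100000L) {
  stopifnot(target > 0, target < 1)
  if (d == 0 && target > alpha)
    stop("unreachable: with zero effect size power never exceeds alpha")
  n <- 2L
  while (pairedTPower(n, d, alpha) < target) {
    n <- n + 1L
    if (n > n_max) stop("no n <= ", n_max, " reaches power ", target)
  }
  n
}
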