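#' Sample size for a chi-square test of association
#'
#' Smallest integer `N` such that a chi-square test of association at
#' significance level `alpha` with `df` degrees of freedom reaches the
#' target power against an alternative of effect size `w` (Cohen's w), for
#' which the test statistic is noncentral chi-square with noncentrality
#' `N * w^2`.
#'
#' For the pathway-by-outcome design (three diagnostic pathways, binary
#' stage or side outcome) `df = 2`; `df` must nonetheless be stated
#' explicitly because the result depends on it.
#'
#' @param w Effect size (Cohen's w), > 0.
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param df Degrees of freedom of the test (default 2).
#' @return Integer sample size.
#' @examples
#' chisq_sample_size(w = 0.1, alpha = 0.05, power = 0.80, df = 2)
#' chisq_sample_size(w = 0.1, alpha = 0.05, power = 0.90, df = 2)
#' @export
chisq_sample_size <- function(w, alpha = 0.05, power = 0.80, df = 2) {
  if (w <= 0) stop("effect size w must be positive", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, df >= 1)
  crit <- qchisq(1 - alpha, df)
  attained <- function(n) {
    pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
  }
  upper <- 10 / w^2
  while (attained(upper) < power) upper <- upper * 2
  root <- uniroot(function(n) attained(n) - power, c(1e-6, upper),
                  tol = 1e-8)$root
  n <- ceiling(root - 1e-9)
  # guard against floating-point edge at the ceiling boundary
  while (attained(n) < power) n <- n + 1L
  as.integer(n)
}
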