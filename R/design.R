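#' Bonferroni family-wise significance threshold
#'
#' Per-test significance threshold controlling the family-wise error rate
#' over a two-way grid of tests (for example all SNP-by-expression pairs).
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests_a,n_tests_b Counts of tests along each axis; the family
#'   size is their product. Use `n_tests_b = 1` for a one-way correction.
#' @param digits Significant digits to which the threshold is reported
#'   (default 3, matching how such thresholds are usually printed).
#'
#' @return Per-test threshold, rounded to `digits` significant digits.
#'
#' @examples
#' bonferroni_threshold(0.05, 675350, 12808)  # 5.78e-12
#' bonferroni_threshold(0.05, 10, 12808)      # 3.9e-7
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests_a = 1, n_tests_b = 1,
                                 digits = 3) {
  stopifnot(alpha > 0, alpha <= 1, n_tests_a >= 1, n_tests_b >= 1)
  signif(alpha / (n_tests_a * n_tests_b), digits)
}

#' Minimum detectable R-squared at a significance level
#'
#' Smallest fraction of expression variance a SNP effect must explain to
#' reach significance `alpha` in a one-way test with `df1` numerator
#' degrees of freedom at sample size `n`. Obtained by inverting the
#' central F distribution: the critical F at (df1, n - df1 - 1) is mapped
#' back to the R-squared scale via R2 = df1 F / (df1 F + n - df1 - 1).
#'
#' @param alpha Per-test significance level.
#' @param n Sample size.
#' @param df1 Numerator degrees of freedom (1 for an additive or
#'   two-group contrast).
#'
#' @return Minimum detectable R-squared.
#' @export
min_detectable_r2 <- function(alpha, n, df1 = 1) {
  stopifnot(alpha > 0, alpha <= 1, n > df1 + 1)
  if (alpha >= 1) return(0)
  df2 <- n - df1 - 1
  f_crit <- qf(alpha, df1, df2, lower.tail = FALSE)
  df1 * f_crit / (df1 * f_crit + df2)
}

#' Analytic power for a single SNP-expression association
#'
#' Power of the one-way F test to detect a SNP explaining a fraction `r2`
#' of expression variance at sample size `n` and per-test level `alpha`.
#' Uses the noncentral F tail with noncentrality n r2 / (1 - r2).
#'
#' @inheritParams min_detectable_r2
#' @param r2 True fraction of expression variance explained, in [0, 1).
#'
#' @return Power in [0, 1].
#' @export
power_single_snp <- function(n, alpha, r2, df1 = 1) {
  stopifnot(r2 >= 0, r2 < 1, n > df1 + 1, alpha > 0, alpha <= 1)
  df2 <- n - df1 - 1
  f_crit <- qf(alpha, df1, df2, lower.tail = FALSE)
  ncp <- n * r2 / (1 - r2)
  pf(f_crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}
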