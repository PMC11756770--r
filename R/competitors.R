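#' Competitor global tests on one p-value or Z-score vector
#'
#' The comparison battery operating on the same per-SNP summary
#' statistics as the dependence-adjusted test: Bonferroni Min-P, Simes,
#' and the Cauchy combination (analytic p-values), plus the
#' Monte-Carlo-calibrated statistics G-Null (independence l-values,
#' correlated null), Sum-chi2, and CPMA.
#'
#' @name competitors
NULL

clip_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' @describeIn competitors Bonferroni-corrected minimum p-value,
#'   `min(1, D * pi_(1))`.
#' @param pvalues numeric vector of per-trait two-sided p-values.
#' @export
minp_test <- function(pvalues) {
  if (length(pvalues) == 0L) abort("empty p-value vector.", class = "adelle_bad_argument")
  min(1, length(pvalues) * min(pvalues))
}

#' @describeIn competitors Simes combination,
#'   `min_d pi_(d) * D / d`. Never exceeds the Min-P p-value.
#' @export
simes_test <- function(pvalues) {
  if (length(pvalues) == 0L) abort("empty p-value vector.", class = "adelle_bad_argument")
  D <- length(pvalues)
  ps <- sort(pvalues, method = "radix")
  min(ps * D / seq_len(D))
}

#' @describeIn competitors Cauchy combination,
#'   `F_C(mean(F_C^{-1}(pi_d)))` with `F_C` the standard Cauchy cdf;
#'   p-values are clipped to `(1e-300, 1 - 1e-16)` before the quantile
#'   transform.
#' @export
cauchy_test <- function(pvalues) {
  if (length(pvalues) == 0L) abort("empty p-value vector.", class = "adelle_bad_argument")
  pcauchy(mean(qcauchy(clip_p(pvalues))))
}

#' @describeIn competitors the ELL statistic with independence
#'   (Beta) l-values; the p-value comes from the Monte Carlo null under
#'   the estimated correlation (`method = "gnull"` stream).
#' @param q truncation fraction for the ELL statistic.
#' @param null an `adelle_mc_null` carrying the `"gnull"` stream.
#' @export
gnull_test <- function(pvalues, q = 0.2, null) {
  st <- ell_statistic(pvalues, q = q)
  p <- monte_carlo_pvalue(log(st$T), null, method = "gnull")
  list(method = "gnull", statistic = st$T, p = p, argmin_d = st$argmin_d)
}

#' @describeIn competitors sum of squared Z scores; Monte Carlo p-value
#'   under the estimated correlation (`chisq = TRUE` gives the analytic
#'   chi-square p, valid only for uncorrelated traits).
#' @param z numeric vector of Z scores.
#' @param chisq use the analytic `chi^2_D` tail instead of Monte Carlo.
#' @export
sumchi2_test <- function(z, null = NULL, chisq = FALSE) {
  stat <- sum(z^2)
  p <- if (chisq) {
    pchisq(stat, df = length(z), lower.tail = FALSE)
  } else {
    if (is.null(null)) abort("Monte Carlo null required unless chisq = TRUE.",
      class = "adelle_bad_argument")
    monte_carlo_pvalue(-stat, null, method = "sumchi2")
  }
  list(method = "sumchi2", statistic = stat, p = p)
}

# CPMA likelihood-ratio statistic per row of a p-value matrix: model
# -log(pi_d) ~ iid Exponential(lambda), test lambda = 1 vs lambda != 1.
# 2[l(lambda-hat) - l(1)] with l(lambda) = D log lambda - lambda sum x.
cpma_statistic_rows <- function(P) {
  X <- -log(clip_p(P))
  D <- ncol(P)
  sx <- rowSums(X)
  lam <- D / sx
  2 * (D * log(lam) - D + sx)
}

#' @describeIn competitors CPMA likelihood-ratio statistic for
#'   exponentially-tilted p-values; Monte Carlo p-value (the chi-square
#'   null does not hold for correlated traits).
#' @export
cpma_test <- function(pvalues, null) {
  if (length(pvalues) == 0L) abort("empty p-value vector.", class = "adelle_bad_argument")
  stat <- cpma_statistic_rows(matrix(pvalues, nrow = 1L))
  p <- monte_carlo_pvalue(-stat, null, method = "cpma")
  list(method = "cpma", statistic = stat, p = p)
}
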