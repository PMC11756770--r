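#' Dependence-adjusted l-values for one SNP's Z-score vector
#'
#' Converts Z scores to two-sided p-values `pi = 2 Phi(-|Z|)`, sorts them,
#' and evaluates the dependent-traits order-statistic null cdf exactly at
#' each of the first `xi` order statistics (the precompute grid supplies
#' the correlation summary; no interpolation is used for reported values).
#'
#' @param z numeric vector of Z scores, length equal to the grid's trait
#'   count.
#' @param grid an `adelle_null_grid` for the SNP's trans trait set.
#' @return numeric vector of `xi` l-values.
#' @export
adelle_lvalues <- function(z, grid) {
  stopifnot(inherits(grid, "adelle_null_grid"))
  if (length(z) != grid$D) {
    abort(
      sprintf("Z vector has length %d but the grid was built for D = %d.",
              length(z), grid$D),
      class = "adelle_bad_argument"
    )
  }
  if (anyNA(z)) abort("Z scores must not contain NA here; drop missing traits and rebuild the grid.",
    class = "adelle_bad_argument")
  p <- pmax(2 * pnorm(-abs(z)), 1e-300)
  ps <- sort(p, method = "radix")[seq_len(grid$xi)]
  exact_order_stat_cdf(ps, grid)
}

#' Minimum l-value statistic
#'
#' @param lvalues numeric vector of l-values for ranks `1..xi`.
#' @return list with `T` (the minimum) and `argmin_d` (smallest rank
#'   attaining it).
#' @export
adelle_statistic <- function(lvalues) {
  if (length(lvalues) == 0L) abort("empty l-value vector.", class = "adelle_bad_argument")
  arg <- which.min(lvalues)
  list(T = lvalues[[arg]], argmin_d = as.integer(arg))
}

#' Convert association test statistics to null-standard-normal Z scores
#'
#' t statistics map through `qnorm(pt(.))`; signed chi-square (1 df)
#' statistics map to `sign * sqrt(chi2)`.
#'
#' @param stat statistic value(s).
#' @param kind `"t"` or `"chi2_with_sign"`.
#' @param df degrees of freedom (t only); typically `N - k - 1`.
#' @param sign effect sign(s), `+1`/`-1` (chi2 only).
#' @return Z score(s), approximately N(0,1) under the per-trait null.
#' @export
transform_to_z <- function(stat, kind = c("t", "chi2_with_sign"), df = NULL,
                           sign = NULL) {
  kind <- match.arg(kind)
  if (kind == "t") {
    if (is.null(df) || any(df < 1)) {
      abort("`df` must be >= 1 for t statistics.", class = "adelle_bad_argument")
    }
    # evaluate in the lower tail for numerical stability, restore the sign
    lower <- pt(-abs(stat), df, log.p = TRUE)
    z <- -qnorm(lower, log.p = TRUE)
    return(base::sign(stat) * z)
  }
  if (any(stat < 0)) abort("chi-square statistics must be >= 0.", class = "adelle_bad_argument")
  if (is.null(sign) || !all(abs(sign) == 1)) {
    abort("`sign` of +/-1 required for chi2_with_sign.", class = "adelle_bad_argument")
  }
  sign * sqrt(stat)
}

#' ADELLE global test for a single SNP
#'
#' Computes the dependence-adjusted l-values, the minimum-l statistic, and
#' a Monte Carlo p-value against a pre-simulated null.
#'
#' @param z Z-score vector for one SNP across its trans traits.
#' @param grid `adelle_null_grid` for the trait set.
#' @param null `adelle_mc_null` simulated with [monte_carlo_null()] from
#'   the matching correlation (must carry the `"adelle"` method).
#' @param snp_id optional label.
#' @return an `adelle_test` object (list with `snp_id`, `D`, `T`, `p`,
#'   `R`, `method`, `argmin_d`, `lvalues`).
#' @export
adelle_test <- function(z, grid, null, snp_id = NA_character_) {
  stopifnot(inherits(null, "adelle_mc_null"))
  if (!identical(null$fingerprint, grid$fingerprint)) {
    abort("Monte Carlo null and grid were built from different correlation matrices.",
      class = "adelle_bad_argument"
    )
  }
  lv <- adelle_lvalues(z, grid)
  st <- adelle_statistic(lv)
  p <- monte_carlo_pvalue(log(st$T), null, method = "adelle")
  structure(
    list(
      snp_id = snp_id, D = grid$D, T = st$T, p = p, R = null$R,
      method = "adelle", argmin_d = st$argmin_d, lvalues = lv,
      q = grid$q
    ),
    class = "adelle_test"
  )
}

#' @export
print.adelle_test <- function(x, ...) {
  cat(sprintf(
    "<adelle_test> %s: D = %d, T = %.4g (argmin d = %d), Monte Carlo p = %.4g (R = %d)\n",
    ifelse(is.na(x$snp_id), "(unnamed SNP)", x$snp_id),
    x$D, x$T, x$argmin_d, x$p, x$R
  ))
  invisible(x)
}
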