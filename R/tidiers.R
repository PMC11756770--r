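#' Tidy the l-values of a single-SNP global test
#'
#' @param x an `adelle_test`.
#' @param ... unused.
#' @return tibble with one row per order-statistic rank: `d`, `lvalue`,
#'   and whether the rank attained the test statistic.
#' @export
tidy.adelle_test <- function(x, ...) {
  tibble(
    d = seq_along(x$lvalues),
    lvalue = x$lvalues,
    at_minimum = seq_along(x$lvalues) == x$argmin_d
  )
}

#' One-row summary of a single-SNP global test
#'
#' @param x an `adelle_test`.
#' @param ... unused.
#' @export
glance.adelle_test <- function(x, ...) {
  tibble(
    snp = x$snp_id, method = x$method, D = x$D, q = x$q,
    statistic = x$T, argmin_d = x$argmin_d, p.value = x$p, R = x$R
  )
}

#' @export
tidy.adelle_scan <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.adelle_scan <- function(x, ...) {
  md <- attr(x, "metadata")
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$method),
    n_snps = dplyr::n(),
    n_discoveries = sum(.data$discovery),
    min_p = min(.data$p),
    .groups = "drop"
  ) |>
    dplyr::mutate(q = md$q, R = md$R, fdr = md$fdr, w = md$w)
}
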