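#' Beta l-value of a p-value order statistic
#'
#' Under the global null with independent traits, the d-th smallest of D
#' p-values follows a Beta(d, D - d + 1) distribution. The l-value is the
#' left-tail probability of the observed order statistic under that law:
#' small l-values mean the d-th smallest p-value is smaller than expected.
#'
#' @param p_sorted numeric vector of order-statistic values in `[0, 1]`.
#' @param d integer rank(s) of the order statistic(s), in `1..D`. Recycled
#'   against `p_sorted`.
#' @param D total number of p-values.
#' @return numeric vector of l-values in `[0, 1]`.
#' @examples
#' beta_lvalue(0.01, 1, 10) # 1 - 0.99^10
#' @export
beta_lvalue <- function(p_sorted, d, D) {
  stopifnot(is.numeric(p_sorted), is.numeric(d), length(D) == 1L, D >= 1)
  if (any(d < 1 | d > D)) {
    abort("`d` must lie in [1, D].", class = "adelle_bad_argument")
  }
  if (any(p_sorted < 0 | p_sorted > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "adelle_bad_argument")
  }
  pbeta(p_sorted, d, D - d + 1)
}

#' Truncation configuration for ELL-type statistics
#'
#' The ELL and ADELLE statistics use only the smallest fraction `q` of the
#' p-values for a SNP: order statistics of rank `1..xi` with
#' `xi = floor(q * D)`. A configuration with `q * D < 1` is rejected rather
#' than silently falling back to a single order statistic.
#'
#' @param q truncation fraction in (0, 1]. Default 0.2.
#' @param D number of trans traits.
#' @return a list with elements `q`, `D`, `xi`.
#' @export
ell_config <- function(q = 0.2, D) {
  stopifnot(length(q) == 1L, length(D) == 1L)
  if (!is.finite(q) || q <= 0 || q > 1) {
    abort("`q` must lie in (0, 1].", class = "adelle_bad_argument")
  }
  xi <- floor(q * D)
  if (xi < 1) {
    abort(
      sprintf("q * D = %.3g < 1: no order statistics to use; increase q or D.", q * D),
      class = "adelle_bad_argument"
    )
  }
  list(q = q, D = as.integer(D), xi = as.integer(xi))
}

#' ELL test statistic for independent traits
#'
#' Sorts the p-values, computes Beta l-values for the first
#' `xi = floor(q D)` order statistics, and returns the minimum l-value.
#'
#' @param pvalues numeric vector of per-trait p-values.
#' @param q truncation fraction (see [ell_config()]).
#' @return list with `T` (the statistic), `lvalues` (length `xi`),
#'   `argmin_d`, `D`, `q`, `xi`.
#' @examples
#' ell_statistic(rep(0.5, 5), q = 1)$T # 0.5^5
#' @export
ell_statistic <- function(pvalues, q = 0.2) {
  if (length(pvalues) == 0L) {
    abort("empty p-value vector.", class = "adelle_bad_argument")
  }
  if (anyNA(pvalues)) {
    abort("p-values must not contain NA.", class = "adelle_bad_argument")
  }
  D <- length(pvalues)
  cfg <- ell_config(q, D)
  ps <- sort(pvalues, method = "radix")[seq_len(cfg$xi)]
  lv <- beta_lvalue(ps, seq_len(cfg$xi), D)
  arg <- which.min(lv)
  list(
    T = lv[[arg]], lvalues = lv, argmin_d = as.integer(arg),
    D = D, q = q, xi = cfg$xi
  )
}

#' Rejection boundary of the ELL test at a given local level
#'
#' The ELL test rejects when any of the first `xi` order statistics falls
#' below the Beta quantile at the local level `eta`; ranks beyond `xi` get a
#' zero boundary (never rejected on).
#'
#' @param eta local level in (0, 1).
#' @param D number of p-values.
#' @param xi number of leading order statistics used.
#' @return numeric vector of length `D`: `qbeta(eta, d, D - d + 1)` for
#'   `d <= xi`, zero beyond.
#' @export
ell_boundary <- function(eta, D, xi) {
  stopifnot(length(eta) == 1L, length(D) == 1L, length(xi) == 1L)
  if (!is.finite(eta) || eta <= 0 || eta >= 1) {
    abort("`eta` must lie in (0, 1).", class = "adelle_bad_argument")
  }
  if (xi < 1 || xi > D) {
    abort("`xi` must lie in [1, D].", class = "adelle_bad_argument")
  }
  d <- seq_len(xi)
  c(qbeta(eta, d, D - d + 1), rep(0, D - xi))
}

#' Global level of the ELL test as a function of the local level
#'
#' Computes `alpha(eta) = P(T_ELL < eta)` exactly (to numerical precision)
#' under i.i.d. Uniform(0,1) p-values. The event `T_ELL < eta` is a
#' boundary crossing by the first `xi` uniform order statistics of the Beta
#' quantile boundary at level `eta`; its probability is evaluated by a
#' conditional-binomial recursion over the boundary cells: with
#' `N_j` = number of uniforms at or below boundary point `b_j`, no crossing
#' means `N_j <= j - 1` for all `j <= xi`, and the joint law of the `N_j`
#' chain is a Markov chain of binomial increments.
#'
#' @param eta local level in (0, 1).
#' @param D number of p-values.
#' @param q truncation fraction.
#' @return the global level `alpha` in (0, 1).
#' @export
global_level_from_local <- function(eta, D, q = 0.2) {
  cfg <- ell_config(q, D)
  if (!is.finite(eta) || eta <= 0 || eta >= 1) {
    abort("`eta` must lie in (0, 1).", class = "adelle_bad_argument")
  }
  b <- ell_boundary(eta, D, cfg$xi)[seq_len(cfg$xi)]
  alpha <- 1 - ell_noncrossing_prob(b, D)
  if (!is.finite(alpha)) {
    abort("boundary-crossing recursion failed (non-finite result).",
      class = "adelle_internal_error"
    )
  }
  min(max(alpha, 0), 1)
}

# P(pi_(j) >= b_j for all j = 1..xi) for D iid Uniform(0,1) and a
# nondecreasing boundary b. g[j+1] holds P(N_m = j, N_i <= i-1 for i <= m)
# after processing boundary point m, where N_m counts uniforms <= b_m;
# conditional on N_{m-1} = i the increment is Binomial(D - i, step) with
# step the new cell's mass rescaled to the remaining tail.
ell_noncrossing_prob <- function(b, D) {
  xi <- length(b)
  b <- pmin(pmax(b, 0), 1)
  g <- (1 - b[1])^D                   # N_1 = 0
  if (xi >= 2) {
    for (m in 2:xi) {
      step <- (b[m] - b[m - 1]) / (1 - b[m - 1])
      if (!is.finite(step)) step <- 0 # b[m-1] == 1: no mass left
      i_idx <- 0:(m - 2)              # admissible N_{m-1}
      j_idx <- 0:(m - 1)              # admissible N_m
      k <- outer(j_idx, i_idx, "-")   # increment sizes
      sz <- matrix(rep(D - i_idx, each = m), nrow = m)
      tm <- matrix(0, nrow = m, ncol = m - 1)
      ok <- k >= 0
      tm[ok] <- dbinom(k[ok], sz[ok], step)
      g <- as.vector(tm %*% g)
    }
  }
  sum(g)
}

#' Local level achieving a target global level
#'
#' Inverts [global_level_from_local()] by binary search on `(0, alpha]`
#' (the local level never exceeds the global level when `xi >= 1`).
#'
#' @param alpha target global level in (0, 1).
#' @param D number of p-values.
#' @param q truncation fraction.
#' @param tol absolute tolerance on the achieved global level; default
#'   `1e-4 * alpha`.
#' @param max_iter iteration cap for the binary search.
#' @return the local level `eta` with
#'   `|global_level_from_local(eta, D, q) - alpha| <= tol`.
#' @export
local_level_from_global <- function(alpha, D, q = 0.2, tol = 1e-4 * alpha,
                                    max_iter = 200L) {
  cfg <- ell_config(q, D)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "adelle_bad_argument")
  }
  lo <- 0
  hi <- alpha
  # alpha(eta) is increasing in eta and alpha(alpha) >= alpha, so the root
  # lies in (0, alpha].
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    a <- global_level_from_local(mid, D, q = cfg$q)
    if (abs(a - alpha) <= tol) {
      return(mid)
    }
    if (a < alpha) lo <- mid else hi <- mid
  }
  a <- global_level_from_local((lo + hi) / 2, D, q = cfg$q)
  if (abs(a - alpha) <= tol) {
    return((lo + hi) / 2)
  }
  abort("binary search for the local level did not converge.",
    class = "adelle_internal_error"
  )
}
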