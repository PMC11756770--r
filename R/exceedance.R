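#' Joint two-sided exceedance probability for a correlated pair
#'
#' `P(|Z1| >= c, |Z2| >= c)` for a standard bivariate normal pair with
#' correlation `rho`. Symmetric in `rho -> -rho`. Evaluated by reducing the
#' orthant probability to a one-dimensional integral,
#' `P(Z1 >= c, Z2 >= c) = Int_c^Inf phi(z) Phi((rho z - c)/sqrt(1-rho^2)) dz`,
#' computed with fixed Gauss-Legendre quadrature, vectorised over `rho`.
#'
#' @param c nonnegative scalar threshold on `|Z|`.
#' @param rho correlation(s) in `[-1, 1]` (values within 1e-12 outside are
#'   clipped).
#' @return numeric vector, one probability per `rho`.
#' @export
pair_exceedance <- function(c, rho) {
  stopifnot(length(c) == 1L, is.finite(c), c >= 0)
  if (any(abs(rho) > 1 + 1e-12)) {
    abort("`rho` must lie in [-1, 1].", class = "adelle_bad_argument")
  }
  rho <- pmin(pmax(rho, -1), 1)
  a <- abs(rho)                      # two-sided exceedance depends on |rho|
  out <- numeric(length(rho))
  p <- 2 * pnorm(-c)
  deg <- a >= 1 - 1e-14
  out[deg] <- p                      # |rho| = 1: events coincide
  ind <- a <= 1e-14
  out[ind] <- p^2                    # independence
  mid <- !deg & !ind
  if (any(mid)) {
    r <- a[mid]
    # P(|Z1|>=c,|Z2|>=c) = 2 [ Q(rho) + Q(-rho) ] with Q the upper orthant.
    out[mid] <- 2 * (bvn_orthant(c, r) + bvn_orthant(c, -r))
  }
  pmin(pmax(out, 0), 1)
}

# Upper orthant P(Z1 >= c, Z2 >= c) for correlation(s) rho, |rho| < 1.
# Gauss-Legendre on [c, c + 9] (integrand ~ phi decays below 1e-18 there).
bvn_orthant <- function(c, rho) {
  gl <- gauss_legendre_nodes(128L, c, c + 9)
  z <- gl$x
  s <- sqrt(1 - rho^2)
  # nodes x rho: Phi((rho z - c)/s), phi(z) weights
  arg <- (outer(z, rho) - c) / rep(s, each = length(z))
  val <- pnorm(arg) * dnorm(z)
  colSums(val * gl$w)
}

# Cached Gauss-Legendre nodes on [-1, 1], rescaled to [a, b].
gl_cache <- new.env(parent = emptyenv())
gauss_legendre_nodes <- function(n, a, b) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  g <- gl_cache[[key]]
  list(x = (b - a) / 2 * g$x + (a + b) / 2, w = (b - a) / 2 * g$w)
}

#' Null moments of the exceedance count S(c)
#'
#' `S(c)` counts traits with `|Z_d| >= c`. Under the multivariate normal
#' null its mean is the binomial mean `D * 2 * Phi(-c)` regardless of the
#' correlations, while its variance picks up a pairwise term:
#' `Var = D p (1-p) + sum_{i != j} (P(|Z_i|>=c, |Z_j|>=c) - p^2)`.
#' The pairwise sum is evaluated over a binned histogram of off-diagonal
#' correlations (bin count set in [build_null_grid()]'s caller or here),
#' with each occupied bin represented by its mean correlation.
#'
#' @param c threshold on `|Z|`.
#' @param omega a `trait_correlation` (or plain correlation matrix).
#' @param bins number of equal-width histogram bins on `[-1, 1]` for the
#'   off-diagonal correlations.
#' @return list with `c`, `p` (= `2 Phi(-c)`), `mean`, `variance`, `D`.
#' @export
null_moments_S <- function(c, omega, bins = 2000L) {
  omega <- as_trait_correlation(omega)
  hist <- rho_histogram(omega, bins)
  null_moments_from_hist(c, hist, omega$D)
}

# Off-diagonal correlation histogram reused across thresholds: counts and
# mean rho per occupied bin.
rho_histogram <- function(omega, bins = 2000L) {
  if (inherits(omega, "trait_correlation")) omega <- omega$omega
  off <- omega[row(omega) < col(omega)]          # each unordered pair once
  idx <- pmin(pmax(ceiling((off + 1) / 2 * bins), 1L), bins)
  cnt <- tabulate(idx, nbins = bins)
  occ <- which(cnt > 0L)
  sums <- vapply(
    split(off, factor(idx, levels = occ)),
    sum, numeric(1)
  )
  list(rho = sums / cnt[occ], n_pairs = cnt[occ])
}

null_moments_from_hist <- function(c, hist, D) {
  p <- 2 * pnorm(-c)
  mean_S <- D * p
  excess <- if (length(hist$rho)) {
    pe <- pair_exceedance(c, hist$rho)
    2 * sum(hist$n_pairs * (pe - p^2))           # both (i,j) orders
  } else {
    0
  }
  variance <- D * p * (1 - p) + excess
  list(c = c, p = p, mean = mean_S, variance = max(variance, 0), D = D)
}

#' Moment-matched beta-binomial null for the exceedance count
#'
#' Fits `BB(D, lambda, gamma)` by the method of moments to the mean and
#' variance of `S(c)`. Writing `mu = mean/D` and the pairwise
#' over-dispersion `phi = (variance / (D mu (1-mu)) - 1) / (D - 1)`, the
#' match is `lambda + gamma = (1 - phi)/phi`, `lambda = mu (lambda+gamma)`.
#' With no excess variance (`phi <= 0`, e.g. uncorrelated traits) the exact
#' Binomial(D, mu) is used instead (`fallback_binomial = TRUE`).
#'
#' @param m moments list as returned by [null_moments_S()].
#' @return list with `D`, `mu`, `lambda`, `gamma`, `fallback_binomial`.
#' @export
fit_beta_binomial <- function(m) {
  D <- m$D
  mu <- m$mean / D
  if (mu <= 0 || mu >= 1) {
    # degenerate threshold: S(c) is a.s. 0 (or D); treat as binomial
    return(list(D = D, mu = mu, lambda = NA_real_, gamma = NA_real_,
                fallback_binomial = TRUE))
  }
  vb <- D * mu * (1 - mu)
  phi <- (m$variance / vb - 1) / (D - 1)
  if (phi >= 1) {
    abort(
      "variance exceeds the maximum attainable beta-binomial variance; correlation input looks broken.",
      class = "adelle_bad_argument"
    )
  }
  # negligible variance inflation (including exact zero up to rounding):
  # the beta-binomial degenerates to the binomial, and the matched
  # (lambda, gamma) would be too large to evaluate stably
  if (phi <= 0 || phi * (D - 1) < 1e-6) {
    return(list(D = D, mu = mu, lambda = NA_real_, gamma = NA_real_,
                fallback_binomial = TRUE))
  }
  s <- (1 - phi) / phi
  list(
    D = D, mu = mu, lambda = mu * s, gamma = (1 - mu) * s,
    fallback_binomial = FALSE
  )
}

# log upper tail P(S >= d) for d = 1..dmax under the fitted null.
# Each tail is a shifted log-sum-exp of the exact pmf terms, so extreme
# tails (l-values ~ 1e-16) keep full relative precision.
bb_log_tail <- function(fit, dmax) {
  D <- fit$D
  if (fit$fallback_binomial) {
    return(pbinom(seq_len(dmax) - 1L, D, fit$mu, lower.tail = FALSE, log.p = TRUE))
  }
  k <- 0:D
  lpmf <- lchoose(D, k) + lbeta(k + fit$lambda, D - k + fit$gamma) -
    lbeta(fit$lambda, fit$gamma)
  vapply(seq_len(dmax), function(d) {
    lp <- lpmf[(d + 1L):(D + 1L)]
    m <- max(lp)
    if (is.infinite(m)) m else m + log(sum(exp(lp - m)))
  }, numeric(1))
}

#' Null cdf of a p-value order statistic under dependent traits
#'
#' `F_(d)(h) = P(pi_(d) <= h)` under the null, using the event identity
#' that at least `d` p-values fall at or below `h` exactly when the
#' exceedance count at `c = -qnorm(h/2)` is at least `d`. The count's null
#' distribution is the moment-matched beta-binomial (exact binomial when
#' the traits are uncorrelated, in which case this reduces to the Beta cdf
#' `pbeta(h, d, D - d + 1)`).
#'
#' @param h threshold in (0, 1), scalar.
#' @param d order-statistic rank(s).
#' @param omega a `trait_correlation` or correlation matrix.
#' @param bins histogram bins for the pairwise variance sum.
#' @return `P(pi_(d) <= h)` for each `d`.
#' @export
order_stat_cdf <- function(h, d, omega, bins = 2000L) {
  stopifnot(length(h) == 1L, h > 0, h < 1)
  omega <- as_trait_correlation(omega)
  if (any(d < 1 | d > omega$D)) {
    abort("`d` must lie in [1, D].", class = "adelle_bad_argument")
  }
  c <- -qnorm(h / 2)
  m <- null_moments_S(c, omega, bins = bins)
  fit <- fit_beta_binomial(m)
  if (fit$fallback_binomial) {
    return(pbeta(h, d, omega$D - d + 1))  # exact binomial-tail/Beta identity
  }
  exp(bb_log_tail(fit, max(d))[d])
}
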