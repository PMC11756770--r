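#' Precompute the dependent-traits order-statistic null cdf on a grid
#'
#' Builds the reusable precompute table for one trait set: for each
#' threshold `h` in a dense grid `H`, the beta-binomial approximation to
#' the exceedance-count distribution at `c = -qnorm(h/2)` is fitted once
#' and `F_(d)(h)` filled for `d = 1..xi`. The grid is log-spaced in `h`
#' over the extreme tail (where l-value accuracy matters most) and
#' completed with equally spaced thresholds on the `|Z|` scale up to
#' `h` near 1, so the statistic of an entirely null-looking Z vector is
#' still representable. Monte Carlo replicates interpolate `log F_(d)`
#' linearly on the `|Z|`-threshold scale; reported l-values for observed
#' data are computed exactly (see [adelle_lvalues()]).
#'
#' @param omega a `trait_correlation` from [shrink_correlation()], or a
#'   plain correlation matrix (used as-is).
#' @param q truncation fraction; `xi = floor(q D)` rows are tabulated.
#' @param n_tail number of log-spaced tail grid points.
#' @param n_bulk number of bulk grid points (linear in `|Z|` threshold).
#' @param h_min smallest tabulated threshold.
#' @param bins histogram bins for the pairwise variance sum.
#' @return an object of class `adelle_null_grid`.
#' @export
build_null_grid <- function(omega, q = 0.2, n_tail = 600L, n_bulk = 240L,
                            h_min = 1e-16, bins = 2000L) {
  omega <- as_trait_correlation(omega)
  cfg <- ell_config(q, omega$D)
  if (n_tail < 2L || h_min <= 0 || h_min >= 1) {
    abort("invalid grid specification.", class = "adelle_bad_argument")
  }
  hist <- rho_histogram(omega, bins)
  D <- omega$D
  # The pairwise variance-excess term is smooth and log-quadratic-ish in
  # the |Z| threshold; evaluate the O(bins) quadrature on a coarse grid
  # of thresholds once and spline log(excess), instead of re-running it
  # for every tabulated threshold.
  excess_fun <- make_excess_fun(hist, D)
  moments_at <- function(c) capped_moments(c, excess_fun, D)

  f1 <- function(h) {
    fit <- fit_beta_binomial(moments_at(-qnorm(h / 2)))
    if (fit$fallback_binomial) pbeta(h, 1, D) else exp(bb_log_tail(fit, 1L)[1L])
  }
  # h at which the smallest p-value's null cdf reaches 1/2
  h_half <- stats::uniroot(
    function(lh) f1(exp(lh)) - 0.5,
    lower = log(1e-10), upper = log(0.99), tol = 1e-10
  )$root
  h_half <- exp(h_half)

  h_tail <- exp(seq(log(h_min), log(h_half), length.out = n_tail))
  c_half <- -qnorm(h_half / 2)
  c_bulk <- seq(c_half, 1e-3, length.out = n_bulk + 1L)[-1L]
  h <- sort(unique(c(h_tail, 2 * pnorm(-c_bulk))))
  cg <- -qnorm(h / 2)

  logF <- matrix(NA_real_, nrow = cfg$xi, ncol = length(h))
  for (j in seq_along(h)) {
    fit <- fit_beta_binomial(moments_at(cg[j]))
    logF[, j] <- if (fit$fallback_binomial) {
      pbeta(h[j], seq_len(cfg$xi), D - seq_len(cfg$xi) + 1, log.p = TRUE)
    } else {
      bb_log_tail(fit, cfg$xi)
    }
  }
  # guard against quadrature/rounding-level violations of monotonicity
  # and of the log-probability bound
  logF <- pmin(t(apply(logF, 1L, cummax)), 0)

  structure(
    list(
      h = h, c = cg, logF = logF, D = D, q = q, xi = cfg$xi,
      w = omega$w, bins = bins, rho_hist = hist, excess_fun = excess_fun,
      fingerprint = omega$fingerprint
    ),
    class = "adelle_null_grid"
  )
}

# Spline of the log pairwise variance excess of S(c) over the threshold
# range; returns a function c -> excess (0 when there is none).
make_excess_fun <- function(hist, D, c_lo = 1e-3, c_hi = 8.6, n = 81L) {
  cs <- seq(c_lo, c_hi, length.out = n)
  ex <- vapply(cs, function(c) {
    m <- null_moments_from_hist(c, hist, D)
    m$variance - D * m$p * (1 - m$p)
  }, numeric(1))
  if (all(ex <= 1e-12)) {
    return(function(c) rep(0, length(c)))
  }
  lsp <- stats::splinefun(cs, log(pmax(ex, 1e-300)), method = "natural")
  # beyond c_hi the natural spline extrapolates the (declining) log
  # excess linearly; below c_lo clamp to the bulk value
  function(c) exp(lsp(pmax(c, c_lo)))
}

#' @export
print.adelle_null_grid <- function(x, ...) {
  cat(sprintf(
    "<adelle_null_grid> D = %d, q = %.3g (xi = %d), %d thresholds in [%.3g, %.3g]\n",
    x$D, x$q, x$xi, length(x$h), min(x$h), max(x$h)
  ))
  invisible(x)
}

# Interpolated log F_(d) at the d-th largest |Z| per replicate.
# `topk` is a B x xi matrix (descending |Z| per row). Values beyond the
# tabulated tail (p below the grid floor) are recomputed exactly; values
# below the smallest tabulated threshold clamp to it (l-value ~ 1).
grid_log_lvalues <- function(topk, grid) {
  xi <- grid$xi
  stopifnot(ncol(topk) == xi)
  B <- nrow(topk)
  out <- matrix(NA_real_, B, xi)
  for (d in seq_len(xi)) {
    out[, d] <- approx(grid$c, grid$logF[d, ], xout = topk[, d], rule = 2)$y
  }
  over <- which(topk[, 1L] > max(grid$c))
  for (r in over) {
    h_r <- 2 * pnorm(-topk[r, ])
    out[r, ] <- log(exact_order_stat_cdf(h_r, grid))
  }
  out
}

# F_(d)(h_d) for one replicate's vector of thresholds (length xi),
# evaluated at the exact thresholds (no grid interpolation), with the
# variance excess from the grid's spline.
exact_order_stat_cdf <- function(h_vec, grid) {
  h_vec <- pmax(h_vec, 1e-300)
  D <- grid$D
  vapply(seq_along(h_vec), function(d) {
    fit <- fit_beta_binomial(
      capped_moments(-qnorm(h_vec[d] / 2), grid$excess_fun, D)
    )
    if (fit$fallback_binomial) {
      pbeta(h_vec[d], d, D - d + 1)
    } else {
      exp(bb_log_tail(fit, d)[d])
    }
  }, numeric(1))
}

# Moments of S(c) with the variance excess kept inside the beta-binomial
# feasibility region (excess < (D-1) * binomial variance): far beyond the
# tabulated threshold range the extrapolated excess dominates a vanishing
# binomial variance, where any over-dispersion value is immaterial for
# the resulting (essentially zero) tail probabilities.
capped_moments <- function(c, excess_fun, D) {
  p <- 2 * pnorm(-c)
  vb <- D * p * (1 - p)
  ex <- min(excess_fun(c), 0.999 * (D - 1) * vb)
  list(c = c, p = p, mean = D * p, variance = max(vb + ex, 0), D = D)
}
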