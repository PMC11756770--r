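# Exceedance-count moments and the beta-binomial null approximation.

test_that("pair exceedance matches closed forms at the correlation extremes", {
  for (c in c(0.5, 1.96, 3)) {
    p <- 2 * pnorm(-c)
    expect_equal(pair_exceedance(c, 0), p^2, tolerance = 1e-12)
    expect_equal(pair_exceedance(c, 1), p, tolerance = 1e-12)
    expect_equal(pair_exceedance(c, -1), p, tolerance = 1e-12)
  }
})

test_that("pair exceedance agrees with adaptive quadrature and is even in rho", {
  oracle <- function(c, rho) {
    f <- function(z) dnorm(z) * pnorm((rho * z - c) / sqrt(1 - rho^2))
    g <- function(z) dnorm(z) * pnorm((-rho * z - c) / sqrt(1 - rho^2))
    2 * (integrate(f, c, Inf, rel.tol = 1e-12)$value +
      integrate(g, c, Inf, rel.tol = 1e-12)$value)
  }
  for (case in list(c(1.96, 0.5), c(1, 0.2), c(3, -0.7), c(0.1, 0.9))) {
    expect_equal(pair_exceedance(case[1], case[2]), oracle(case[1], case[2]),
      tolerance = 1e-10
    )
  }
  rhos <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(pair_exceedance(2, rhos), pair_exceedance(2, -rhos))
})

test_that("pair exceedance matches Monte Carlo at rho = 0.5, c = 1.96", {
  set.seed(11)
  n <- 1e6
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  hit <- abs(z1) >= 1.96 & abs(z2) >= 1.96
  mc <- mean(hit)
  se <- sd(hit) / sqrt(n)
  expect_equal(pair_exceedance(1.96, 0.5), mc, tolerance = 3 * se / mc)
})

test_that("null moments: binomial mean always, binomial variance iff uncorrelated", {
  D <- 50
  p <- 2 * pnorm(-1.5)
  m_id <- null_moments_S(1.5, diag(D))
  expect_equal(m_id$mean, D * p)
  expect_equal(m_id$variance, D * p * (1 - p), tolerance = 1e-10)
  m_eq <- null_moments_S(1.5, equicorr(D, 0.4))
  expect_equal(m_eq$mean, m_id$mean) # mean ignores off-diagonals
  expect_gt(m_eq$variance, m_id$variance) # strict over-dispersion
})

test_that("null variance of S(c) matches simulation for an equicorrelated trio", {
  D <- 3
  Om <- equicorr(D, 0.5)
  m <- null_moments_S(1, Om)
  set.seed(12)
  Z <- matrix(rnorm(1e6 * D), ncol = D) %*% chol(Om)
  S <- rowSums(abs(Z) >= 1)
  expect_equal(m$mean, mean(S), tolerance = 3 * sd(S) / sqrt(1e6) / m$mean)
  dev <- (S - mean(S))^2
  expect_equal(m$variance, var(S), tolerance = 3 * sd(dev) / sqrt(1e6) / m$variance)
})

test_that("beta-binomial moment match round-trips and degenerates sensibly", {
  # binomial variance: exact fallback
  D <- 100
  p <- 0.05
  fit0 <- fit_beta_binomial(list(D = D, mean = D * p, variance = D * p * (1 - p)))
  expect_true(fit0$fallback_binomial)
  # over-dispersed: implied BB mean/variance reproduce the inputs
  fit <- fit_beta_binomial(list(D = 100, mean = 5, variance = 10))
  expect_false(fit$fallback_binomial)
  s <- fit$lambda + fit$gamma
  mu <- fit$lambda / s
  bb_mean <- 100 * mu
  bb_var <- 100 * mu * (1 - mu) * (1 + 99 / (s + 1))
  expect_equal(bb_mean, 5, tolerance = 1e-8)
  expect_equal(bb_var, 10, tolerance = 1e-8)
  # variance above the attainable maximum signals broken input
  expect_error(
    fit_beta_binomial(list(D = 10, mean = 5, variance = 26)),
    class = "adelle_bad_argument"
  )
})

test_that("order-statistic cdf reduces to the Beta cdf for uncorrelated traits", {
  D <- 100
  for (h in c(1e-6, 1e-3, 0.05)) {
    for (d in c(1L, 5L)) {
      expect_equal(order_stat_cdf(h, d, diag(D)), pbeta(h, d, D - d + 1),
        tolerance = 1e-10
      )
    }
  }
})

test_that("order-statistic cdf tracks simulation under strong equicorrelation", {
  D <- 5
  Om <- equicorr(D, 0.6)
  set.seed(13)
  Z <- matrix(rnorm(1e6 * D), ncol = D) %*% chol(Om)
  P <- 2 * pnorm(-abs(Z))
  p2 <- apply(P, 1, function(x) sort(x)[2])
  emp <- mean(p2 <= 0.05)
  se <- sqrt(emp * (1 - emp) / 1e6)
  # beta-binomial approximation slack on top of Monte Carlo error
  expect_equal(order_stat_cdf(0.05, 2, Om), emp, tolerance = (3 * se + 0.005) / emp)
})

test_that("event identity: {pi_(d) <= h} equals {S(c(h)) >= d} replicate by replicate", {
  D <- 20
  Om <- equicorr(D, 0.3)
  set.seed(14)
  Z <- matrix(rnorm(1e5 * D), ncol = D) %*% chol(Om)
  P <- 2 * pnorm(-abs(Z))
  for (h in c(0.01, 0.2)) {
    S <- rowSums(abs(Z) >= -qnorm(h / 2))
    for (d in c(1L, 3L, 8L)) {
      pd <- apply(P, 1, function(x) sort(x, partial = d)[d])
      expect_identical(pd <= h, S >= d)
    }
  }
})

test_that("moment-matched beta-binomial tracks S(c) far better than a binomial", {
  # The beta-binomial is an approximation: its first two moments are
  # matched exactly (checked above against simulation), but under global
  # equicorrelation its cdf can still deviate by a few percent in the
  # centre of the distribution. The test pins down the honest contract:
  # a large improvement over the moment-free binomial, and small error
  # in the upper tail that drives the l-values.
  set.seed(15)
  for (case in list(list(D = 10, rho = 0.5), list(D = 100, rho = 0.2))) {
    Om <- equicorr(case$D, case$rho)
    c0 <- 1.5
    m <- null_moments_S(c0, Om)
    fit <- fit_beta_binomial(m)
    tail_bb <- exp(adelle:::bb_log_tail(fit, case$D))
    Z <- matrix(rnorm(2e5 * case$D), ncol = case$D) %*% chol(Om)
    S <- rowSums(abs(Z) >= c0)
    emp_tail <- vapply(seq_len(case$D), function(d) mean(S >= d), numeric(1))
    p <- m$mean / case$D
    tail_bin <- pbinom(seq_len(case$D) - 1L, case$D, p, lower.tail = FALSE)
    expect_lt(
      max(abs(tail_bb - emp_tail)),
      max(abs(tail_bin - emp_tail)) / 2
    )
    expect_lt(max(abs(tail_bb - emp_tail)), 0.08)
    deep <- emp_tail <= 0.05
    expect_lt(max(abs(tail_bb - emp_tail)[deep]), 0.02)
  }
})
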