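# The dependence-adjusted global test: l-values, statistic, Monte Carlo
# significance, and its invariances.

test_that("identity-correlation l-values equal the independence Beta l-values", {
  set.seed(21)
  D <- 100
  tc <- adelle:::as_trait_correlation(diag(D))
  grid <- build_null_grid(tc, q = 0.2)
  for (i in 1:5) {
    z <- rnorm(D) + sample(c(0, 3), D, replace = TRUE, prob = c(0.95, 0.05))
    lv <- adelle_lvalues(z, grid)
    ref <- ell_statistic(2 * pnorm(-abs(z)), q = 0.2)$lvalues
    expect_equal(lv, ref, tolerance = 1e-10)
  }
})

test_that("degenerate and spiked Z vectors give the expected l-values", {
  D <- 100
  grid <- build_null_grid(adelle:::as_trait_correlation(diag(D)), q = 0.2)
  # all Z = 0: every p-value is 1, every l-value is 1
  expect_equal(adelle_lvalues(rep(0, D), grid), rep(1, 20))
  # one huge Z: l_1 tiny, later l-values in the near-one region
  z <- c(10, rep(0, D - 1))
  lv <- adelle_lvalues(z, grid)
  expect_lt(lv[1], 1e-15)
  expect_true(all(lv[-1] > 0.9))
  expect_error(adelle_lvalues(rep(0, D - 1), grid), class = "adelle_bad_argument")
})

test_that("statistic takes the minimum with ties broken toward small d", {
  expect_equal(adelle_statistic(c(0.3, 0.1, 0.2)), list(T = 0.1, argmin_d = 2L))
  expect_equal(adelle_statistic(rep(0.4, 5))$argmin_d, 1L)
  expect_equal(adelle_statistic(0.7), list(T = 0.7, argmin_d = 1L))
})

test_that("Monte Carlo p-value follows (N(T)+1)/(R+1) with inclusive ties", {
  null <- structure(
    list(stats = list(adelle = sort(log(seq(0.01, 0.99, length.out = 99)))),
         R = 99L, seed = 1L, q = 0.2, fingerprint = "x"),
    class = "adelle_mc_null"
  )
  expect_equal(monte_carlo_pvalue(log(0.005), null), 1 / 100)
  expect_equal(monte_carlo_pvalue(log(1), null), 1)
  # N(T) = 4 -> 0.05
  t5 <- null$stats$adelle[4]
  expect_equal(monte_carlo_pvalue(t5, null), 5 / 100)
})

test_that("Monte Carlo null is reproducible and self-consistent", {
  tc <- adelle:::as_trait_correlation(diag(5))
  g <- build_null_grid(tc, q = 1)
  n1 <- monte_carlo_null(tc, g, R = 300, seed = 5, methods = c("adelle", "gnull"))
  n2 <- monte_carlo_null(tc, g, R = 300, seed = 5, methods = c("adelle", "gnull"))
  expect_identical(n1$stats, n2$stats)
  # batch size must not change the stream
  n3 <- monte_carlo_null(tc, g, R = 300, seed = 5, methods = c("adelle", "gnull"),
                         batch_size = 64L)
  expect_equal(n1$stats, n3$stats)
  # ecdf of the null statistics at its own decile ~ 0.1
  q10 <- quantile(n1$stats$adelle, 0.1)
  expect_equal(mean(n1$stats$adelle <= q10), 0.1, tolerance = 0.02)
})

test_that("p-values are invariant to trait order and Z sign flips", {
  set.seed(23)
  D <- 40
  Om <- equicorr(D, 0.3)
  tc <- adelle:::as_trait_correlation(Om)
  g <- build_null_grid(tc, q = 0.2)
  null <- monte_carlo_null(tc, g, R = 500, seed = 9)
  z <- rnorm(D) + c(rep(2, 4), rep(0, D - 4))
  base <- adelle_test(z, g, null)
  flip <- adelle_test(-z, g, null)
  expect_identical(base$p, flip$p)
  expect_identical(base$T, flip$T)
  # permuting traits together with the correlation leaves the test unchanged
  perm <- sample(D)
  tc_p <- adelle:::as_trait_correlation(Om[perm, perm])
  g_p <- build_null_grid(tc_p, q = 0.2)
  lv_p <- adelle_lvalues(z[perm], g_p)
  expect_equal(lv_p, base$lvalues, tolerance = 1e-12)
})

test_that("with identity correlation, adjusted and independence tests coincide", {
  tc <- adelle:::as_trait_correlation(diag(50))
  g <- build_null_grid(tc, q = 0.2)
  null <- monte_carlo_null(tc, g, R = 400, seed = 17,
                           methods = c("adelle", "gnull"))
  # same draws, same l-values up to the replicate path's grid
  # interpolation; the sorted statistic streams agree to that accuracy
  expect_equal(null$stats$adelle, null$stats$gnull, tolerance = 1e-3)
  set.seed(31)
  for (i in 1:3) {
    z <- rnorm(50)
    ta <- adelle_test(z, g, null)
    tg <- gnull_test(2 * pnorm(-abs(z)), q = 0.2, null = null)
    # exact statistics coincide; Monte Carlo p-values may differ by at
    # most a couple of rank swaps from interpolation at the ties
    expect_equal(log(ta$T), log(tg$statistic), tolerance = 1e-8)
    expect_lt(abs(ta$p - tg$p), 2.5 / (null$R + 1))
  }
})

test_that("t and signed-chi-square statistics transform to null-normal Z", {
  expect_equal(transform_to_z(0, "t", df = 10), 0)
  expect_equal(transform_to_z(4, "chi2_with_sign", sign = -1), -2)
  expect_equal(transform_to_z(2, "t", df = 998), 2, tolerance = 0.01)
  # heavy-tail correction goes the right way at small df
  expect_lt(transform_to_z(3, "t", df = 5), 3)
  expect_error(transform_to_z(1, "t"), class = "adelle_bad_argument")
  expect_error(transform_to_z(-1, "chi2_with_sign", sign = 1),
    class = "adelle_bad_argument")
  # round-trip through simulated t statistics stays uniform
  set.seed(24)
  tstat <- stats::rt(2e4, df = 8)
  z <- transform_to_z(tstat, "t", df = 8)
  ks <- suppressWarnings(stats::ks.test(z, pnorm))
  expect_gt(ks$p.value, 0.001)
})

test_that("Monte Carlo test calibration matches the analytic ELL calibration
           under the identity", {
  # With Omega = I the statistic's null law is the independence one, so
  # P(T < eta) should match alpha(eta) from the exact recursion.
  D <- 50
  q <- 0.2
  tc <- adelle:::as_trait_correlation(diag(D))
  g <- build_null_grid(tc, q = q)
  R <- 1e5
  null <- monte_carlo_null(tc, g, R = R, seed = 41)
  for (alpha in c(0.05, 0.01)) {
    eta <- local_level_from_global(alpha, D, q = q)
    hit <- mean(null$stats$adelle < log(eta))
    se <- sqrt(alpha * (1 - alpha) / R)
    expect_lt(abs(hit - alpha), 3 * se)
  }
})
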