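# Synthetic-data generator and study harness.

test_that("true-correlation structures are valid and match closed forms", {
  expect_identical(gen_true_correlation(6, "identity"), diag(6))
  # equicorrelated spectrum: 1 + (D-1) rho once, 1 - rho repeated
  ev <- eigen(gen_true_correlation(4, "equicorrelated", rho = 0.3),
              symmetric = TRUE)$values
  expect_equal(ev, c(1.9, 0.7, 0.7, 0.7), tolerance = 1e-12)
  expect_error(gen_true_correlation(5, "equicorrelated", rho = -0.3),
    class = "adelle_bad_argument")
  # seeded determinism
  expect_identical(
    gen_true_correlation(30, "random_factor", seed = 8),
    gen_true_correlation(30, "random_factor", seed = 8)
  )
  for (s in c("modular", "random_factor", "block")) {
    Om <- gen_true_correlation(60, s, seed = 2, rho = 0.4,
                               block_sizes = rep(20, 3))
    expect_equal(diag(Om), rep(1, 60))
    expect_identical(Om, t(Om))
    expect_gt(min(eigen(Om, symmetric = TRUE)$values), 0)
  }
  expect_error(gen_true_correlation(10, "block", block_sizes = c(4, 4)),
    class = "adelle_bad_argument")
})

test_that("estimated correlation converges to the truth and records w", {
  Om <- gen_true_correlation(50, "modular", seed = 3)
  est <- estimate_omega_pipeline(Om, N = 1e5, seed = 4)
  expect_lt(max(abs(est$omega - Om)), 0.05)
  expect_true(est$w <= 1 && est$w >= 0)
  est2 <- estimate_omega_pipeline(Om, N = 1e5, seed = 4)
  expect_identical(est$omega, est2$omega)
})

test_that("variance-explained maps to the regression noncentrality", {
  expect_equal(effect_size_from_variance(0, 1000), 0)
  expect_equal(effect_size_from_variance(0.015, 1000),
               sqrt(1000 * 0.015 / 0.985))
  expect_equal(effect_size_from_variance(0.015, 1000), 3.902, tolerance = 1e-3)
  # simulation oracle: simple regression at N = 1000, v = 0.015
  set.seed(31)
  N <- 1000
  v <- 0.015
  nrep <- 2000
  zs <- replicate(nrep, {
    g <- scale(rnorm(N))
    y <- sqrt(v) * g + sqrt(1 - v) * rnorm(N)
    f <- stats::lm.fit(cbind(1, g), y)
    beta <- f$coefficients[2]
    se <- sqrt(sum(f$residuals^2) / (N - 2) / sum((g - mean(g))^2))
    beta / se
  })
  se_mc <- sd(zs) / sqrt(nrep)
  expect_lt(abs(mean(zs) - effect_size_from_variance(v, N)), 3 * se_mc + 0.02)
})

test_that("simulated Z scores honour the mean structure and the seed", {
  Om <- gen_true_correlation(40, "modular", seed = 5)
  Z0 <- simulate_z(Om, R = 2e4, seed = 6)
  # null: standard normal margins
  ks <- suppressWarnings(stats::ks.test(Z0[, 7], pnorm))
  expect_gt(ks$p.value, 0.001)
  Z1 <- simulate_z(Om, R = 2e4, seed = 6, A = 5, c_A = 2.5)
  pos <- attr(Z1, "positions")
  expect_length(pos, 5)
  expect_equal(unname(colMeans(Z1[, pos])), rep(2.5, 5), tolerance = 0.05)
  expect_equal(mean(colMeans(Z1[, -pos])), 0, tolerance = 0.05)
  expect_identical(Z1, simulate_z(Om, R = 2e4, seed = 6, A = 5, c_A = 2.5))
})

test_that("type-1 study refuses levels below the Monte Carlo resolution", {
  expect_error(
    run_type1_study(D = 20, R_sim = 100, R_mc = 100, levels = 1e-4),
    class = "adelle_bad_argument"
  )
})

test_that("type-1 study keeps small-scale calibration inside its bands", {
  t1 <- run_type1_study(
    D = 60, R_sim = 4000, R_mc = 4000, seed = 3,
    levels = 0.05, methods = c("adelle", "minp")
  )
  expect_true(all(t1$inside))
  expect_equal(t1$type1, t1$rejections / 4000)
})

test_that("power study: saturation, null behaviour, and monotonicity in effect", {
  Om <- gen_true_correlation(60, "modular", seed = 12)
  # A = D with huge effects: everything rejects
  pw_sat <- run_power_study(
    settings = data.frame(A = 60L, v = 0.5), omega_true = Om,
    level = 0.01, R_alt = 50L, R_mc = 2000L, seed = 13,
    methods = c("adelle", "minp", "sumchi2")
  )
  expect_true(all(pw_sat$power > 0.99))
  # A = 0 reduces to the null: power near the level
  pw_null <- run_power_study(
    settings = data.frame(A = 0L, v = 0), omega_true = Om,
    level = 0.05, R_alt = 1000L, R_mc = 2000L, seed = 14,
    methods = c("adelle", "minp")
  )
  expect_true(all(abs(pw_null$power - 0.05) < 0.03))
  # power nondecreasing in the effect size (3 grid points, fixed A)
  pw_mono <- run_power_study(
    settings = data.frame(A = c(4L, 4L, 4L), v = c(0.005, 0.02, 0.06)),
    omega_true = Om, level = 0.01, R_alt = 400L, R_mc = 2000L, seed = 15,
    methods = "adelle"
  )
  expect_true(all(diff(pw_mono$power) > -0.05))
  expect_gt(pw_mono$power[3], pw_mono$power[1])
  # relative power is 1 for the per-setting best method
  expect_equal(max(pw_sat$relative_power), 1)
})

test_that("QQ acceptance band has the advertised simultaneous coverage", {
  # n = 1: pointwise two-sided uniform band
  b1 <- qq_acceptance_band(1, level = 0.05)
  expect_equal(b1$lower, 0.025, tolerance = 1e-3)
  expect_equal(b1$upper, 0.975, tolerance = 1e-3)
  n <- 100
  band <- qq_acceptance_band(n, level = 0.05)
  # band contains the expected quantiles
  expect_true(all(band$lower < band$expected & band$expected < band$upper))
  set.seed(71)
  inside <- replicate(1000, {
    u <- sort(runif(n))
    all(u >= band$lower & u <= band$upper)
  })
  cover <- mean(inside)
  # coverage >= 95% by construction (Bonferroni across the two sides),
  # and not conservative by more than ~1%
  expect_gt(cover, 0.95 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(cover, 0.975)
})
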