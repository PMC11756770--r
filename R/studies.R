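#' Acceptance interval for an empirical type-1 error estimate
#'
#' Interval around the nominal level inside which an estimated rejection
#' fraction is consistent with correct calibration. For analytic p-values
#' the interval is the exact binomial one; for Monte-Carlo-calibrated
#' p-values with equal simulation and calibration replicate counts the
#' estimator's variance is doubled, and a normal-approximation interval
#' with variance factor 2 is used.
#'
#' @param level nominal type-1 error level.
#' @param R number of simulation replicates.
#' @param conf confidence of the acceptance interval.
#' @param mc_calibrated whether p-values are Monte Carlo estimates based
#'   on an equal number of calibration replicates.
#' @return numeric `c(lower, upper)`.
#' @export
acceptance_interval <- function(level, R, conf = 0.99, mc_calibrated = FALSE) {
  stopifnot(level > 0, level < 1, R >= 1)
  a <- (1 - conf) / 2
  if (mc_calibrated) {
    half <- qnorm(1 - a) * sqrt(2 * level * (1 - level) / R)
    c(max(0, level - half), min(1, level + half))
  } else {
    c(qbinom(a, R, level), qbinom(1 - a, R, level)) / R
  }
}

#' Type-1 error study under a correlated null
#'
#' Replicates the null-calibration experiment: a true trait correlation
#' is drawn, an estimate is formed from `N` simulated individuals and
#' shrunk toward the identity, and `R_sim` null Z-score vectors from the
#' TRUE correlation are tested using the ESTIMATED one — Monte Carlo
#' methods against `R_mc` calibration replicates (equal counts minimise
#' the variance of the type-1 estimate for a fixed budget), analytic
#' methods directly. Rejection fractions are compared to acceptance
#' intervals around each nominal level.
#'
#' @param D number of traits.
#' @param omega_true true correlation matrix, or `NULL` to draw a
#'   `random_factor` one from the seed.
#' @param N sample size for the correlation-estimation step.
#' @param R_sim,R_mc simulation and Monte Carlo replicate counts.
#' @param q truncation fraction for the l-value methods.
#' @param levels nominal levels to assess.
#' @param methods subset of
#'   `c("adelle","gnull","sumchi2","cpma","minp","simes","cauchy")`.
#' @param seed integer seed driving every random stage.
#' @param conf confidence for the acceptance intervals.
#' @param batch_size replicates per generation batch.
#' @return a tibble with one row per method x level: rejection count,
#'   empirical type-1 error, acceptance bounds, and an `inside` flag.
#' @export
run_type1_study <- function(D = 500L, omega_true = NULL, N = 1000L,
                            R_sim = 10000L, R_mc = R_sim, q = 0.2,
                            levels = c(0.05, 0.01),
                            methods = c("adelle", "gnull", "sumchi2", "cpma",
                                        "minp", "simes", "cauchy"),
                            seed = 1L, conf = 0.99, batch_size = 20000L) {
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  if (any(levels < 1 / (R_mc + 1)) && any(methods %in% mc_methods)) {
    abort(sprintf(
      "smallest resolvable Monte Carlo p-value is 1/(R_mc+1) = %.3g; requested level below it.",
      1 / (R_mc + 1)
    ), class = "adelle_bad_argument")
  }
  if (is.null(omega_true)) {
    omega_true <- gen_true_correlation(D, "modular", seed = child_seed(seed, 1L))
  }
  D <- nrow(omega_true)
  omega_hat <- estimate_omega_pipeline(omega_true, N, seed = child_seed(seed, 2L))
  grid <- build_null_grid(omega_hat, q = q)

  mc_m <- intersect(methods, mc_methods)
  an_m <- intersect(methods, analytic_methods)
  null <- NULL
  if (length(mc_m)) {
    null <- monte_carlo_null(omega_hat, grid, R = R_mc,
                             seed = child_seed(seed, 3L),
                             methods = mc_m, batch_size = batch_size)
  }
  ch_true <- chol(omega_true)
  sim <- replicate_statistics(
    R_sim, grid, methods,
    draw = function(B) rmvn_rows(B, ch_true),
    seed = child_seed(seed, 4L), batch_size = batch_size
  )

  pv <- lapply(setNames(methods, methods), function(m) {
    if (m %in% mc_methods) monte_carlo_pvalue(sim[[m]], null, method = m)
    else sim[[m]]
  })
  out <- tidyr::expand_grid(method = methods, level = levels)
  out <- dplyr::mutate(
    out,
    R_sim = R_sim,
    R_mc = ifelse(.data$method %in% mc_methods, R_mc, NA_integer_),
    rejections = purrr::map2_int(.data$method, .data$level,
                                 ~ sum(pv[[.x]] < .y)),
    type1 = .data$rejections / R_sim
  )
  bounds <- purrr::map2(out$level, out$method, function(l, m) {
    acceptance_interval(l, R_sim, conf = conf,
                        mc_calibrated = m %in% mc_methods)
  })
  out$lower <- purrr::map_dbl(bounds, 1L)
  out$upper <- purrr::map_dbl(bounds, 2L)
  out$inside <- out$type1 >= out$lower & out$type1 <= out$upper
  attr(out, "pvalues") <- pv
  attr(out, "w") <- omega_hat$w
  out
}

#' Power study across sparsity settings
#'
#' For each `(A, v)` setting, simulates Z-score vectors with exactly `A`
#' associated traits at the mean shift implied by variance explained `v`
#' and sample size `N`, and estimates each method's power at the given
#' level. All methods see the same replicate stream within a setting, so
#' cross-method comparisons are paired; two calls with the same seed see
#' the same stream, so across-call comparisons (e.g. different `q`) are
#' paired too.
#'
#' @param settings data frame with columns `A` and `v` (one row per
#'   setting). Default: the six paper-style sparsity settings rescaled to
#'   `D` (ratios `A/D` preserved, `A` at least 1).
#' @param D,omega_true,N,q,seed,batch_size as in [run_type1_study()].
#' @param level significance level for declaring rejection.
#' @param R_alt alternative replicates per setting.
#' @param R_mc Monte Carlo calibration replicates.
#' @param methods methods to compare.
#' @return tibble per setting x method with `power`, binomial 95% CI,
#'   `relative_power` (power / per-setting maximum), and the
#'   per-replicate rejection vector as a list-column `rejected`.
#' @export
run_power_study <- function(settings = NULL, D = 500L, omega_true = NULL,
                            N = 1000L, q = 0.2, level = 0.001,
                            R_alt = 1000L, R_mc = 10000L,
                            methods = c("adelle", "gnull", "sumchi2", "cpma",
                                        "minp", "simes", "cauchy"),
                            seed = 1L, batch_size = 20000L) {
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  if (level < 1 / (R_mc + 1) && any(methods %in% mc_methods)) {
    abort("level below Monte Carlo resolution 1/(R_mc+1).", class = "adelle_bad_argument")
  }
  if (is.null(settings)) settings <- default_power_settings(D)
  if (is.null(omega_true)) {
    omega_true <- gen_true_correlation(D, "modular", seed = child_seed(seed, 1L))
  }
  D <- nrow(omega_true)
  omega_hat <- estimate_omega_pipeline(omega_true, N, seed = child_seed(seed, 2L))
  grid <- build_null_grid(omega_hat, q = q)
  mc_m <- intersect(methods, mc_methods)
  null <- NULL
  if (length(mc_m)) {
    null <- monte_carlo_null(omega_hat, grid, R = R_mc,
                             seed = child_seed(seed, 3L),
                             methods = mc_m, batch_size = batch_size)
  }
  ch_true <- chol(omega_true)

  rows <- purrr::pmap(settings, function(A, v, ...) {
    c_A <- effect_size_from_variance(v, N)
    sseed <- child_seed(seed, 100L + A * 13L + round(1e5 * v))
    set.seed(child_seed(sseed, 7L))
    positions <- sort(sample.int(D, A))
    mu <- numeric(D)
    mu[positions] <- c_A
    sim <- replicate_statistics(
      R_alt, grid, methods,
      draw = function(B) sweep(rmvn_rows(B, ch_true), 2L, mu, "+"),
      seed = sseed, batch_size = batch_size
    )
    purrr::map(setNames(methods, methods), function(m) {
      p <- if (m %in% mc_methods) monte_carlo_pvalue(sim[[m]], null, method = m)
           else sim[[m]]
      p < level
    })
  })

  out <- tidyr::expand_grid(
    dplyr::as_tibble(settings)[, c("A", "v")],
    method = methods
  )
  out$c_A <- effect_size_from_variance(out$v, N)
  out$R <- R_alt
  out$level <- level
  out$rejected <- purrr::map2(
    match(paste(out$A, out$v), paste(settings$A, settings$v)), out$method,
    ~ rows[[.x]][[.y]]
  )
  out$power <- purrr::map_dbl(out$rejected, mean)
  out$se <- sqrt(out$power * (1 - out$power) / R_alt)
  out$ci_lo <- pmax(0, out$power - 1.96 * out$se)
  out$ci_hi <- pmin(1, out$power + 1.96 * out$se)
  out <- dplyr::group_by(out, .data$A, .data$v)
  out <- dplyr::mutate(out, relative_power = .data$power / max(.data$power))
  dplyr::ungroup(out)
}

#' Paper-style sparsity settings rescaled to a smaller trait count
#'
#' The six `(A, v)` pairs used in the power experiments at full scale
#' (`A` of 5, 10, 20, 50, 100, 200 out of 10^4 traits with per-trait
#' variance explained 1.5%, 1%, 0.8%, 0.5%, 0.4%, 0.2%), with `A`
#' rescaled proportionally to `D` (minimum 1) and `v` unchanged so the
#' per-trait signal strength matches the full-scale study.
#'
#' @param D trait count of the reduced study.
#' @return tibble with columns `A`, `v`.
#' @export
default_power_settings <- function(D = 500L) {
  tibble(
    A = pmax(1L, as.integer(round(c(5, 10, 20, 50, 100, 200) * D / 1e4))),
    v = c(0.015, 0.01, 0.008, 0.005, 0.004, 0.002)
  )
}

#' Simultaneous QQ-plot acceptance band from equal local levels
#'
#' Per-order-statistic Beta quantile bands whose simultaneous coverage is
#' `1 - level`, calibrated by the exact ELL global/local level relation
#' (each side carries local level `eta` solving
#' `global_level_from_local(eta, n, q = 1) = level / 2`).
#'
#' @param n number of p-values on the QQ plot.
#' @param level simultaneous non-coverage (default 0.05 for a 95% band).
#' @return tibble with `d`, `expected` (`d/(n+1)`), `lower`, `upper`.
#' @export
qq_acceptance_band <- function(n, level = 0.05) {
  stopifnot(n >= 1)
  eta <- local_level_from_global(level / 2, n, q = 1)
  d <- seq_len(n)
  tibble(
    d = d,
    expected = d / (n + 1),
    lower = qbeta(eta, d, n - d + 1),
    upper = qbeta(1 - eta, d, n - d + 1)
  )
}
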