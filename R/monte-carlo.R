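# Internal statistic orientation: every Monte-Carlo-calibrated method is
# stored so that SMALLER means MORE EXTREME. adelle/gnull use log T (the
# min l-value can underflow on the probability scale); sumchi2 and cpma
# store the negated statistic.
mc_methods <- c("adelle", "gnull", "sumchi2", "cpma")
analytic_methods <- c("minp", "simes", "cauchy")
all_methods <- c(mc_methods, analytic_methods)

#' Monte Carlo null distribution of the global test statistics
#'
#' Simulates `R` null Z-score vectors from `N_D(0, Omega)` (Cholesky
#' factorised once, generated in batches of `batch_size` rows to bound
#' memory) and computes the chosen test statistics on each replicate via
#' the precompute grid. Statistics are returned sorted, oriented so that
#' smaller values are more extreme.
#'
#' @param omega `trait_correlation` (the shrinkage-regularised estimate).
#' @param grid matching `adelle_null_grid`.
#' @param R number of replicates.
#' @param seed integer seed; the replicate stream is reproducible and
#'   independent of `batch_size`.
#' @param methods subset of `c("adelle", "gnull", "sumchi2", "cpma")`.
#' @param batch_size replicates per batch.
#' @return an `adelle_mc_null`: list with sorted statistic vectors in
#'   `$stats`, plus `R`, `seed`, `q`, `fingerprint`.
#' @export
monte_carlo_null <- function(omega, grid, R, seed = 1L,
                             methods = "adelle", batch_size = 10000L) {
  omega <- as_trait_correlation(omega)
  stopifnot(inherits(grid, "adelle_null_grid"), R >= 1)
  if (!identical(omega$fingerprint, grid$fingerprint)) {
    abort("grid was precomputed for a different correlation matrix.",
      class = "adelle_bad_argument"
    )
  }
  methods <- match.arg(methods, mc_methods, several.ok = TRUE)
  ch <- tryCatch(chol(omega$omega), error = function(e) {
    abort("correlation matrix is not positive definite.", class = "adelle_internal_error")
  })
  stats <- replicate_statistics(
    R, grid, methods,
    draw = function(B) rmvn_rows(B, ch),
    seed = seed, batch_size = batch_size
  )
  structure(
    list(
      stats = lapply(stats, sort, method = "radix"),
      R = as.integer(R), seed = seed, q = grid$q,
      fingerprint = grid$fingerprint
    ),
    class = "adelle_mc_null"
  )
}

#' @export
print.adelle_mc_null <- function(x, ...) {
  cat(sprintf(
    "<adelle_mc_null> R = %d replicates, methods: %s (seed %s)\n",
    x$R, paste(names(x$stats), collapse = ", "), format(x$seed)
  ))
  invisible(x)
}

# B rows from N_D(0, t(ch) %*% ch). Each replicate consumes D consecutive
# values of the RNG stream, so results are independent of the batch size.
rmvn_rows <- function(B, ch) {
  t(matrix(rnorm(nrow(ch) * B), nrow(ch))) %*% ch
}

# Shared batched engine: draw(B) returns a B x D matrix of null or
# alternative Z scores; statistics are computed per batch via the grid.
replicate_statistics <- function(R, grid, methods, draw, seed, batch_size) {
  set.seed(seed)
  out <- lapply(setNames(methods, methods), function(m) numeric(R))
  done <- 0L
  while (done < R) {
    B <- min(batch_size, R - done)
    Z <- draw(B)
    sb <- batch_statistics(Z, grid, methods)
    for (m in methods) out[[m]][done + seq_len(B)] <- sb[[m]]
    done <- done + B
  }
  out
}

# Statistics for one batch of Z vectors (B x D), oriented smaller =
# more extreme. Returns a named list of length-B vectors.
batch_statistics <- function(Z, grid, methods) {
  D <- grid$D
  xi <- grid$xi
  out <- list()
  need_topk <- any(c("adelle", "gnull", "minp") %in% methods)
  if (need_topk) {
    topk <- .row_abs_topk(Z, xi)
  }
  if ("adelle" %in% methods) {
    ll <- grid_log_lvalues(topk, grid)
    out$adelle <- row_min(ll)
  }
  if ("gnull" %in% methods) {
    # independence l-values: Beta cdf of the sorted two-sided p-values
    lp <- log(2) + pnorm(-topk, log.p = TRUE)
    lb <- matrix(NA_real_, nrow(Z), xi)
    for (d in seq_len(xi)) {
      lb[, d] <- pbeta(exp(lp[, d]), d, D - d + 1, log.p = TRUE)
    }
    out$gnull <- row_min(lb)
  }
  if ("sumchi2" %in% methods) out$sumchi2 <- -rowSums(Z^2)
  if ("cpma" %in% methods || "cauchy" %in% methods || "simes" %in% methods) {
    P <- 2 * pnorm(-abs(Z))
  }
  if ("cpma" %in% methods) out$cpma <- -cpma_statistic_rows(P)
  if ("minp" %in% methods) {
    out$minp <- pmin(1, D * 2 * pnorm(-topk[, 1L]))
  }
  if ("simes" %in% methods) {
    Ps <- .row_sort_asc(P)
    out$simes <- do.call(pmin, lapply(seq_len(D), function(d) Ps[, d] * D / d))
  }
  if ("cauchy" %in% methods) {
    Pc <- pmin(pmax(P, 1e-300), 1 - 1e-16)
    out$cauchy <- pcauchy(rowMeans(qcauchy(Pc)))
  }
  out
}

row_min <- function(m) {
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Monte Carlo p-value of an observed statistic
#'
#' `(N(T) + 1) / (R + 1)`, where `N(T)` counts null replicate statistics
#' less than or equal to the observed one (statistics oriented so smaller
#' is more extreme). The smallest attainable p-value is `1 / (R + 1)`.
#'
#' @param stat observed statistic(s), on the null object's internal scale
#'   (log T for `adelle`/`gnull`, negated statistic for `sumchi2`/`cpma`).
#' @param null an `adelle_mc_null`.
#' @param method which stored statistic stream to compare against.
#' @return p-value(s) in `[1/(R+1), 1]`.
#' @export
monte_carlo_pvalue <- function(stat, null, method = "adelle") {
  stopifnot(inherits(null, "adelle_mc_null"))
  s <- null$stats[[method]]
  if (is.null(s)) {
    abort(sprintf("Monte Carlo null does not carry method '%s'.", method),
      class = "adelle_bad_argument"
    )
  }
  (findInterval(stat, s) + 1) / (null$R + 1)
}
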