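#' Sample correlation matrix of expression traits
#'
#' Pearson correlations across individuals, the raw ingredient for the
#' regularised trait correlation used by the dependent-traits null model.
#'
#' @param expr numeric matrix or data frame, individuals in rows, traits in
#'   columns. Column names are kept as trait IDs.
#' @return a D x D correlation matrix with unit diagonal.
#' @export
estimate_trait_correlation <- function(expr) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) abort("`expr` must be numeric.", class = "adelle_bad_argument")
  if (nrow(expr) < 3L) {
    abort("need at least 3 individuals to estimate trait correlations.",
      class = "adelle_bad_argument"
    )
  }
  sds <- apply(expr, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(expr)[sds == 0] %||% which(sds == 0)
    abort(
      paste0(
        "constant trait column(s): ",
        paste(utils::head(bad, 5L), collapse = ", ")
      ),
      class = "adelle_bad_argument"
    )
  }
  C <- cor(expr)
  C[row(C) == col(C)] <- 1
  (C + t(C)) / 2
}

#' Shrink a trait correlation matrix toward the identity
#'
#' Regularises a (possibly rank-deficient) sample correlation matrix as
#' `Omega = w * C + (1 - w) * I`, guaranteeing positive definiteness for
#' `w < 1` (smallest eigenvalue at least `1 - w`). With `w = "auto"` and the
#' expression matrix supplied, the weight is the Schafer-Strimmer analytic
#' shrinkage intensity toward the identity target:
#' `w = 1 - sum(Var-hat(r_ij)) / sum(r_ij^2)` over off-diagonal entries,
#' clipped to `[0, 1]`.
#'
#' @param C sample correlation matrix.
#' @param w shrinkage weight in `[0, 1]`, or `"auto"` (requires `expr`).
#' @param expr the individuals x traits matrix `C` was estimated from;
#'   needed only for `w = "auto"`.
#' @return an object of class `trait_correlation`: list with `omega`
#'   (the shrunk matrix), `w`, `D`, `source`, and `fingerprint` (a hash
#'   tying downstream precomputations to this matrix).
#' @export
shrink_correlation <- function(C, w = "auto", expr = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) abort("`C` must be square.", class = "adelle_bad_argument")
  if (identical(w, "auto")) {
    if (is.null(expr)) {
      abort("w = \"auto\" requires the expression matrix `expr`.",
        class = "adelle_bad_argument"
      )
    }
    w <- shrinkage_weight(as.matrix(expr))
    src <- "sample estimate (auto shrinkage)"
  } else {
    if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
      abort("`w` must be in [0, 1] or \"auto\".", class = "adelle_bad_argument")
    }
    src <- "supplied weight"
  }
  D <- nrow(C)
  omega <- w * C + (1 - w) * diag(D)
  omega[row(omega) == col(omega)] <- 1
  dimnames(omega) <- dimnames(C)
  structure(
    list(
      omega = omega, w = w, D = D, source = src,
      fingerprint = correlation_fingerprint(omega)
    ),
    class = "trait_correlation"
  )
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat(sprintf(
    "<trait_correlation> D = %d, w = %.4f (%s), fingerprint %s\n",
    x$D, x$w, x$source, x$fingerprint
  ))
  invisible(x)
}

# Second-moment-matched shrinkage intensity toward the identity. The
# weight is chosen so that the aggregate squared off-diagonal correlation
# of w*C — the quantity that governs the over-dispersion of the
# exceedance count, and hence the tail calibration of the Monte Carlo
# null — is an approximately unbiased estimate of the true aggregate:
# E[r_ij^2] = rho_ij^2 + Var(r_ij), so w^2 = 1 - sum Var-hat / sum r^2.
# MSE-optimal (Schafer-Strimmer-type) intensities shrink harder and bias
# the estimated dependence down, which makes Monte-Carlo-calibrated
# p-values anti-conservative. Any w < 1 also restores positive
# definiteness when N << D.
shrinkage_weight <- function(expr) {
  N <- nrow(expr)
  if (N < 3L) abort("need N >= 3 for auto shrinkage.", class = "adelle_bad_argument")
  X <- scale(expr)                       # standardised traits
  R <- crossprod(X) / (N - 1)            # sample correlations
  # A full-rank, well-conditioned sample correlation needs no
  # regularisation, and any w < 1 biases every pairwise correlation
  # toward zero — which thins the far tail of the Monte Carlo null and
  # makes extreme p-values anti-conservative. Shrink only when the
  # estimate is (near-)singular, i.e. when N is not comfortably above D.
  if (N > ncol(X)) {
    ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 1e-6) return(1)
  }
  # Var-hat(r_ij) = N/(N-1)^3 * sum_k (w_kij - wbar_ij)^2 with w_kij the
  # standardised cross-products; sum_k w_kij = (N-1) r_ij.
  M2 <- crossprod(X^2)                   # sum_k w_kij^2
  V <- N / (N - 1)^3 * (M2 - (N - 1)^2 * R^2 / N)
  off <- row(R) != col(R)
  lam <- sum(V[off]) / sum(R[off]^2)
  sqrt(1 - min(max(lam, 0), 1))
}

# Cheap deterministic fingerprint of a correlation matrix: dimensions plus
# a few digests of the off-diagonal entries.
correlation_fingerprint <- function(omega) {
  off <- omega[row(omega) < col(omega)]
  probe <- c(
    nrow(omega), length(off),
    round(sum(off), 10), round(sum(off^2), 10),
    round(sum(abs(off) * seq_along(off) %% 97), 8)
  )
  paste(format(probe, digits = 12, trim = TRUE), collapse = "/")
}

# Coerce user input (matrix or trait_correlation) into trait_correlation.
as_trait_correlation <- function(omega, w = 1) {
  if (inherits(omega, "trait_correlation")) {
    return(omega)
  }
  omega <- as.matrix(omega)
  out <- shrink_correlation(omega, w = w)
  out$source <- "supplied"
  out
}
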