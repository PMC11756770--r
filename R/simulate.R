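#' Generate a true trait correlation matrix for simulation studies
#'
#' Structures: `modular` (the studies' default: strong small
#' co-expression blocks mixed with a weak dense factor background —
#' pairwise correlations are mostly weak, as in genome-wide expression
#' panels, yet the exceedance count is clearly over-dispersed);
#' `identity`; `equicorrelated` (common correlation `rho`);
#' `random_factor` (a k-factor loading model `LL' + I` normalised to unit
#' diagonal); `block` (equicorrelated diagonal blocks, zero between
#' blocks).
#'
#' @param D number of traits.
#' @param structure one of `"modular"`, `"identity"`, `"equicorrelated"`,
#'   `"random_factor"`, `"block"`.
#' @param seed integer seed (modular/random_factor draw randomness).
#' @param rho common correlation (equicorrelated/block).
#' @param k number of latent factors (random_factor/modular background).
#' @param loading_sd standard deviation of factor loadings
#'   (random_factor); default 0.5 yields typical `|rho|` around 0.2.
#' @param block_sizes integer vector of block sizes summing to `D`.
#' @return D x D correlation matrix.
#' @export
gen_true_correlation <- function(D,
                                 structure = c("modular", "identity",
                                               "equicorrelated",
                                               "random_factor", "block"),
                                 seed = 1L, rho = 0.3, k = 10L,
                                 loading_sd = 0.5, block_sizes = NULL) {
  structure <- match.arg(structure)
  switch(structure,
    modular = {
      # 20-trait modules at within-module correlation 0.6 (trailing block
      # absorbs any remainder), on a weak dense background (k factors,
      # loading sd 0.15), mixed 60/40 and renormalised.
      sizes <- rep(20L, D %/% 20L)
      if (D %% 20L) sizes <- c(sizes, D %% 20L)
      blocks <- gen_true_correlation(D, "block", rho = 0.6, block_sizes = sizes)
      bg <- gen_true_correlation(D, "random_factor", seed = seed, k = k,
                                 loading_sd = 0.15)
      m <- stats::cov2cor(0.6 * blocks + 0.4 * bg)
      (m + t(m)) / 2
    },
    identity = diag(D),
    equicorrelated = {
      if (rho <= -1 / (D - 1) || rho >= 1) {
        abort(sprintf("equicorrelation requires rho in (-1/(D-1), 1) = (%.4g, 1).",
                      -1 / (D - 1)), class = "adelle_bad_argument")
      }
      m <- matrix(rho, D, D)
      diag(m) <- 1
      m
    },
    random_factor = {
      set.seed(seed)
      L <- matrix(rnorm(D * k, sd = loading_sd), D, k)
      S <- stats::cov2cor(tcrossprod(L) + diag(D))
      (S + t(S)) / 2
    },
    block = {
      if (is.null(block_sizes) || sum(block_sizes) != D) {
        abort("`block_sizes` must sum to D.", class = "adelle_bad_argument")
      }
      if (rho <= -1 / (max(block_sizes) - 1) || rho >= 1) {
        abort("infeasible within-block correlation.", class = "adelle_bad_argument")
      }
      blocks <- lapply(block_sizes, function(s) {
        m <- matrix(rho, s, s)
        diag(m) <- 1
        m
      })
      as.matrix(Matrix_bdiag(blocks))
    }
  )
}

# block-diagonal without importing Matrix
Matrix_bdiag <- function(blocks) {
  D <- sum(vapply(blocks, nrow, integer(1)))
  out <- matrix(0, D, D)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

#' Estimate and regularise the trait correlation from simulated expression
#'
#' Mirrors the analysis pipeline inside simulation studies: draw `N`
#' individuals' trait values from `N_D(0, Omega_true)`, estimate the
#' sample correlation, and shrink it toward the identity. The returned
#' estimate (deliberately different from the truth, as in a real study)
#' is what downstream calibration uses.
#'
#' @param omega_true true correlation matrix.
#' @param N sample size.
#' @param seed integer seed.
#' @param w shrinkage weight or `"auto"`.
#' @return a `trait_correlation`.
#' @export
estimate_omega_pipeline <- function(omega_true, N, seed = 1L, w = "auto") {
  set.seed(seed)
  D <- nrow(omega_true)
  ch <- chol(omega_true)
  expr <- matrix(rnorm(N * D), N) %*% ch
  C <- estimate_trait_correlation(expr)
  shrink_correlation(C, w = w, expr = expr)
}

#' Per-trait mean shift implied by a variance-explained target
#'
#' For a simple regression of a unit-variance trait on a standardised
#' predictor explaining fraction `v` of the trait's variance at sample
#' size `N`, the association Z score has noncentrality
#' `c_A = sqrt(N v / (1 - v))`.
#'
#' @param v proportion of variance explained per associated trait.
#' @param N association-study sample size.
#' @return the mean shift `c_A`.
#' @examples
#' effect_size_from_variance(0.015, 1000) # ~ 3.902
#' @export
effect_size_from_variance <- function(v, N) {
  stopifnot(all(v >= 0), all(v < 1), N >= 2)
  sqrt(N * v / (1 - v))
}

#' Simulate per-SNP Z-score vectors under the null or an alternative
#'
#' Draws `R` vectors `Z ~ N_D(mu, Omega_true)`, where `mu` is zero under
#' the null, or has exactly `A` entries equal to `c_A` under the
#' alternative. The associated trait positions are drawn once from the
#' seed and fixed across replicates.
#'
#' @param omega_true correlation matrix used to generate the scores.
#' @param R number of replicates.
#' @param seed integer seed.
#' @param A number of associated traits (0 for the null).
#' @param c_A mean shift for associated traits.
#' @param positions optional fixed positions of the associated traits.
#' @return an `R x D` matrix of Z scores; associated positions as
#'   attribute `"positions"`.
#' @export
simulate_z <- function(omega_true, R, seed = 1L, A = 0L, c_A = 0,
                       positions = NULL) {
  D <- nrow(omega_true)
  stopifnot(A >= 0, A <= D, c_A >= 0)
  set.seed(child_seed(seed, 7L))
  if (A > 0L && is.null(positions)) {
    positions <- sort(sample.int(D, A))
  }
  mu <- numeric(D)
  if (A > 0L) mu[positions] <- c_A
  set.seed(seed)
  ch <- chol(omega_true)
  Z <- matrix(rnorm(R * D), R) %*% ch
  if (A > 0L) Z <- sweep(Z, 2L, mu, "+")
  attr(Z, "positions") <- positions
  Z
}
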