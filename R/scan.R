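#' Genome scan: one global trans-association test per SNP
#'
#' For every SNP, tests the global null hypothesis that it is associated
#' with none of its trans expression traits. SNPs are grouped by distinct
#' trans trait set (in practice by chromosome, further split by
#' missing-data pattern); each group gets one precompute grid and one
#' Monte Carlo null, shared by all its SNPs. Discoveries are flagged by
#' Benjamini-Hochberg FDR across SNPs within each method.
#'
#' @param zmat numeric traits x SNPs matrix of association Z scores
#'   (dimnames required), e.g. from [read_summary_stats()]. `NA` entries
#'   shrink the SNP's trait set.
#' @param snp_ann,gene_ann annotation tables (see [build_trans_mask()]).
#' @param omega full-panel trait correlation: a `trait_correlation`, a
#'   correlation matrix, or an individuals x traits expression matrix
#'   (`expr = TRUE`), with trait names matching `zmat` rows.
#' @param expr whether `omega` is an expression matrix to estimate and
#'   shrink from.
#' @param q truncation fraction.
#' @param R Monte Carlo replicates per trait-set group.
#' @param seed integer seed.
#' @param fdr FDR level for discovery flags.
#' @param methods methods to run; `"all"` expands to the full battery.
#' @param trans_rule,min_distance_mb trans definition (see
#'   [build_trans_mask()]).
#' @return an `adelle_scan` tibble: one row per SNP x method with
#'   `snp`, `chrom`, `D_m`, `method`, `statistic`, `argmin_d`, `p`,
#'   `discovery`. Run metadata in `attr(, "metadata")`.
#' @export
scan_snps <- function(zmat, snp_ann, gene_ann, omega, expr = FALSE,
                      q = 0.2, R = 10000L, seed = 1L, fdr = 0.05,
                      methods = "adelle",
                      trans_rule = c("different_chromosome", "min_distance"),
                      min_distance_mb = 5) {
  trans_rule <- match.arg(trans_rule)
  if (identical(methods, "all")) methods <- all_methods
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  stopifnot(is.matrix(zmat), !is.null(rownames(zmat)), !is.null(colnames(zmat)))

  if (expr) {
    C <- estimate_trait_correlation(omega)
    omega <- shrink_correlation(C, w = "auto", expr = omega)
  } else {
    omega <- as_trait_correlation(omega)
  }
  if (is.null(rownames(omega$omega))) {
    if (omega$D != nrow(zmat)) {
      abort("unnamed correlation matrix must match zmat's trait dimension.",
        class = "adelle_bad_argument")
    }
    dimnames(omega$omega) <- list(rownames(zmat), rownames(zmat))
  }

  mask <- build_trans_mask(snp_ann, gene_ann, rule = trans_rule,
                           min_distance_mb = min_distance_mb)
  mask <- mask[mask$snp %in% colnames(zmat), ]
  chrom_of <- setNames(snp_ann$chrom, snp_ann$id)

  # effective trait set per SNP: trans genes with observed Z
  mask$traits <- purrr::map2(mask$traits, mask$snp, function(tr, s) {
    tr <- intersect(tr, rownames(zmat))
    tr[!is.na(zmat[tr, s])]
  })
  empty <- lengths(mask$traits) == 0L
  if (any(empty)) {
    warn(sprintf("skipping %d SNP(s) with empty trans trait set.", sum(empty)))
    mask <- mask[!empty, ]
  }
  key <- vapply(mask$traits, function(tr) paste(tr, collapse = "\r"), character(1))
  groups <- split(seq_len(nrow(mask)), key)

  mc_m <- intersect(methods, mc_methods)
  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    traits <- mask$traits[[idx[1L]]]
    sub <- omega$omega[traits, traits, drop = FALSE]
    sub_tc <- structure(
      list(omega = sub, w = omega$w, D = length(traits),
           source = omega$source,
           fingerprint = correlation_fingerprint(sub)),
      class = "trait_correlation"
    )
    grid <- build_null_grid(sub_tc, q = q)
    null <- if (length(mc_m)) {
      monte_carlo_null(sub_tc, grid, R = R,
                       seed = child_seed(seed, 10L + gi), methods = mc_m)
    }
    res[[gi]] <- purrr::map_dfr(idx, function(i) {
      s <- mask$snp[[i]]
      z <- zmat[traits, s]
      scan_one_snp(s, chrom_of[[s]], z, grid, null, methods, q)
    })
  }
  out <- dplyr::bind_rows(res)
  out <- dplyr::group_by(out, .data$method)
  out <- dplyr::mutate(out, discovery = bh_fdr(.data$p, fdr))
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$method, .data$p, .data$snp)
  attr(out, "metadata") <- list(
    q = q, R = R, seed = seed, fdr = fdr, w = omega$w,
    trans_rule = trans_rule, min_distance_mb = min_distance_mb,
    methods = methods, n_groups = length(groups),
    version = as.character(utils::packageVersion("adelle"))
  )
  class(out) <- c("adelle_scan", class(out))
  out
}

scan_one_snp <- function(snp, chrom, z, grid, null, methods, q) {
  p2 <- pmax(2 * pnorm(-abs(z)), 1e-300)
  rows <- purrr::map(methods, function(m) {
    if (m == "adelle") {
      tst <- adelle_test(z, grid, null, snp_id = snp)
      tibble(statistic = tst$T, argmin_d = tst$argmin_d, p = tst$p)
    } else if (m == "gnull") {
      g <- gnull_test(p2, q = q, null = null)
      tibble(statistic = g$statistic, argmin_d = g$argmin_d, p = g$p)
    } else if (m == "sumchi2") {
      s <- sumchi2_test(z, null = null)
      tibble(statistic = s$statistic, argmin_d = NA_integer_, p = s$p)
    } else if (m == "cpma") {
      s <- cpma_test(p2, null = null)
      tibble(statistic = as.numeric(s$statistic), argmin_d = NA_integer_, p = as.numeric(s$p))
    } else if (m == "minp") {
      tibble(statistic = min(p2), argmin_d = 1L, p = minp_test(p2))
    } else if (m == "simes") {
      tibble(statistic = NA_real_, argmin_d = NA_integer_, p = simes_test(p2))
    } else {
      tibble(statistic = NA_real_, argmin_d = NA_integer_, p = cauchy_test(p2))
    }
  })
  dplyr::bind_cols(
    tibble(snp = snp, chrom = chrom, D_m = length(z),
           method = methods),
    dplyr::bind_rows(rows)
  )
}
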