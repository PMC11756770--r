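#' Read per-SNP association summary statistics
#'
#' Accepts three tab-separated encodings: `wide_z` (traits in rows, SNPs
#' in columns, first column the trait ID), `long_z` (columns `trait`,
#' `snp`, `z`), and `long_p_sign` (columns `trait`, `snp`, `p`, `sign`;
#' converted via `Z = -sign * qnorm(p / 2)`). Absent (trait, SNP) pairs in
#' long formats become `NA` and are tracked as missing.
#'
#' @param path file path.
#' @param format one of `"wide_z"`, `"long_z"`, `"long_p_sign"`.
#' @return numeric traits x SNPs matrix with dimnames.
#' @export
read_summary_stats <- function(path, format = c("wide_z", "long_z", "long_p_sign")) {
  format <- match.arg(format)
  if (format == "wide_z") {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(tb[, -1L, drop = FALSE])
    rownames(m) <- as.character(tb[[1L]])
    storage.mode(m) <- "double"
    return(m)
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  need <- if (format == "long_z") c("trait", "snp", "z") else c("trait", "snp", "p", "sign")
  if (!all(need %in% names(tb))) {
    abort(sprintf("expected columns: %s", paste(need, collapse = ", ")),
      class = "adelle_bad_argument"
    )
  }
  dup <- duplicated(tb[, c("trait", "snp")])
  if (any(dup)) {
    abort(sprintf("duplicate (trait, snp) pair at data line %d.", which(dup)[1L]),
      class = "adelle_bad_argument"
    )
  }
  if (format == "long_p_sign") {
    bad <- which(tb$p <= 0 | tb$p > 1)
    if (length(bad)) {
      abort(sprintf("p-value outside (0, 1] at data line %d.", bad[1L]),
        class = "adelle_bad_argument"
      )
    }
    if (!all(abs(tb$sign) == 1)) {
      abort("`sign` must be +1 or -1.", class = "adelle_bad_argument")
    }
    tb$z <- -tb$sign * qnorm(tb$p / 2)
  }
  traits <- unique(tb$trait)
  snps <- unique(tb$snp)
  m <- matrix(NA_real_, length(traits), length(snps),
    dimnames = list(traits, snps)
  )
  m[cbind(match(tb$trait, traits), match(tb$snp, snps))] <- tb$z
  m
}

#' Trans trait sets per SNP from chromosome annotations
#'
#' Under the `different_chromosome` rule a gene is trans to a SNP exactly
#' when they sit on different chromosomes; under `min_distance` a gene on
#' the same chromosome also counts when its nearest edge is more than
#' `min_distance_mb` megabases from the SNP. Gene coordinates are 0-based
#' half-open (BED convention); SNP positions 1-based.
#'
#' @param snp_ann data frame with columns `id`, `chrom`, `pos`.
#' @param gene_ann data frame with columns `id`, `chrom`, `start`, `end`.
#' @param rule `"different_chromosome"` or `"min_distance"`.
#' @param min_distance_mb distance threshold in Mb (min_distance rule).
#' @return tibble with `snp` and a list-column `traits` of gene IDs.
#' @export
build_trans_mask <- function(snp_ann, gene_ann,
                             rule = c("different_chromosome", "min_distance"),
                             min_distance_mb = 5) {
  rule <- match.arg(rule)
  snp_ann <- as_tibble(snp_ann)
  gene_ann <- as_tibble(gene_ann)
  if (anyNA(snp_ann$chrom) || anyNA(gene_ann$chrom)) {
    abort("unknown chromosome in annotations.", class = "adelle_bad_argument")
  }
  if (anyDuplicated(snp_ann$id) || anyDuplicated(gene_ann$id)) {
    abort("annotation IDs must be unique.", class = "adelle_bad_argument")
  }
  traits <- purrr::pmap(snp_ann, function(id, chrom, pos, ...) {
    diff_chr <- gene_ann$chrom != chrom
    if (rule == "different_chromosome") {
      gene_ann$id[diff_chr]
    } else {
      s0 <- pos - 1 # SNP as 0-based point
      dist <- pmax(gene_ann$start - s0, s0 - (gene_ann$end - 1), 0)
      gene_ann$id[diff_chr | dist > min_distance_mb * 1e6]
    }
  })
  tibble(snp = snp_ann$id, traits = traits)
}

#' Benjamini-Hochberg discovery flags
#'
#' @param pvalues numeric vector.
#' @param level target false discovery rate.
#' @return logical vector: discovery at the given FDR.
#' @export
bh_fdr <- function(pvalues, level = 0.05) {
  stopifnot(level > 0, level < 1)
  if (length(pvalues) == 0L) return(logical(0))
  p.adjust(pvalues, method = "BH") <= level
}

#' Write a scan result table / run metadata
#'
#' Results go to a tab-separated file sorted by p-value then SNP ID;
#' metadata (configuration, seeds, shrinkage weight, fingerprints) to
#' JSON. Byte-identical output for identical inputs and seed.
#'
#' @param results tibble from [scan_snps()].
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  out <- dplyr::arrange(results, .data$p, .data$snp)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @param metadata named list.
#' @export
write_metadata <- function(metadata, path) {
  jsonlite::write_json(metadata, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
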