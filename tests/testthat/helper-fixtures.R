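# Shared fixtures built in code; all randomness seeded.

equicorr <- function(D, rho) {
  m <- matrix(rho, D, D)
  diag(m) <- 1
  m
}

# Small synthetic eQTL study: traits with chromosome annotations, SNPs on
# 3 chromosomes, Z-score matrix with one planted trans signal.
make_scan_fixture <- function(seed = 42L, D = 60L, n_snps = 24L,
                              planted_snp = NULL, A = 12L, c_A = 3.2) {
  set.seed(seed)
  if (is.null(planted_snp)) {
    planted_snp <- sprintf("s%02d", min(7L, n_snps))
  }
  gene_ann <- tibble::tibble(
    id = sprintf("g%02d", seq_len(D)),
    chrom = rep(c("chr1", "chr2", "chr3"), length.out = D),
    start = 1000L * seq_len(D),
    end = 1000L * seq_len(D) + 500L
  )
  snp_ann <- tibble::tibble(
    id = sprintf("s%02d", seq_len(n_snps)),
    chrom = rep(c("chr1", "chr2", "chr3"), length.out = n_snps),
    pos = 5000L * seq_len(n_snps)
  )
  omega_true <- gen_true_correlation(D, "random_factor", seed = seed, k = 4L)
  ch <- chol(omega_true)
  Z <- t(matrix(rnorm(n_snps * D), n_snps) %*% ch) # traits x snps
  dimnames(Z) <- list(gene_ann$id, snp_ann$id)
  # plant weak signals on trans traits of the planted SNP
  snp_chr <- snp_ann$chrom[snp_ann$id == planted_snp]
  trans_traits <- gene_ann$id[gene_ann$chrom != snp_chr]
  hit <- sample(trans_traits, min(A, length(trans_traits)))
  Z[hit, planted_snp] <- Z[hit, planted_snp] + c_A
  expr <- matrix(rnorm(300 * D), 300) %*% ch
  colnames(expr) <- gene_ann$id
  list(
    Z = Z, snp_ann = snp_ann, gene_ann = gene_ann, expr = expr,
    omega_true = omega_true, planted_snp = planted_snp, hit = hit
  )
}
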