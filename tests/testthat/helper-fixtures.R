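# Shared fixtures built in code: tiny cohorts and hand-made matrices.

# A small cohort with one planted cis effect, one trans effect and one
# smoking effect; sized for fast unit tests.
tiny_config <- function(seed = 11, n_samples = 300, ld_rho = 0.4) {
  sim_config(
    n_samples = n_samples, n_snps = 120, n_genes = 12,
    chrom_lengths = c("1" = 1.5e8, "2" = 1.2e8, "3" = 1e8),
    ld_block_size = 6, ld_rho = ld_rho,
    cis_effects = data.frame(gene = "G0001", snp = "rs00005", r2 = 0.2),
    trans_effects = data.frame(gene = "G0002", snp = "rs00050", r2 = 0.15),
    rf_effects = data.frame(gene = "G0003", rf = "smoking", r2 = 0.1),
    seed = seed)
}

# Deterministic genotype matrix with given dosage columns.
make_geno <- function(codes, chrom = "1", pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("rs%05d", seq_len(ncol(codes)))
  rownames(codes) <- sprintf("S%04d", seq_len(nrow(codes)))
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 1e4
  genotype_matrix(codes, data.frame(snp = colnames(codes),
                                    chrom = rep(chrom, ncol(codes)),
                                    pos = pos))
}

# Expression matrix from a plain samples x genes matrix with stub
# annotation on chromosome 1.
make_expr <- function(values, chrom = "1") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%04d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  g <- ncol(values)
  expression_matrix(values,
                    data.frame(gene = colnames(values),
                               chrom = rep(chrom, g),
                               start = seq_len(g) * 1e6,
                               end = seq_len(g) * 1e6 + 5e4))
}
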