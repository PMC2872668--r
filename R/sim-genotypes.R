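#' Simulate genotypes in Hardy-Weinberg equilibrium with block LD
#'
#' Each SNP follows Hardy-Weinberg proportions at its assigned minor
#' allele frequency. Linkage disequilibrium within a block is induced by
#' a latent Gaussian copula: a per-block exchangeable multivariate
#' normal with correlation `ld_rho` is thresholded at the HWE quantiles
#' of each SNP, so the marginal genotype distribution is exactly HWE
#' while neighbouring SNPs are correlated. `ld_rho = 0` gives
#' independent SNPs.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; `snp_meta` carries chromosome,
#'   position, design MAF and LD-block index.
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  ids <- sim_ids(config)
  n <- config$n_samples
  set.seed(derive_seed(config$seed, "genotypes"))

  rho <- config$ld_rho
  codes <- matrix(NA_integer_, n, config$n_snps,
                  dimnames = list(ids$samples, ids$snps))
  for (b in unique(layout$snp_meta$block)) {
    idx <- which(layout$snp_meta$block == b)
    shared <- rnorm(n)
    z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(rnorm(n * length(idx)), n, length(idx))
    p <- layout$snp_meta$maf[idx]
    # HWE thresholds on the latent scale: P(0)=(1-p)^2, P(2)=p^2
    z1 <- qnorm((1 - p)^2)
    z2 <- qnorm(1 - p^2)
    g <- sweep(z, 2, z1, ">") + sweep(z, 2, z2, ">")
    codes[, idx] <- g
  }
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(codes)) < config$missing_rate,
                   nrow = n)
    codes[mask] <- NA_integer_
  }
  genotype_matrix(codes, layout$snp_meta)
}
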