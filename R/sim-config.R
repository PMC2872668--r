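#' Simulation configuration
#'
#' Describes a synthetic cohort: genotypes in Hardy-Weinberg
#' equilibrium arranged in LD blocks, risk-factor covariates drawn from
#' the reference cohort distribution, and gene expression built from
#' planted additive genotype effects, risk-factor effects, optional
#' genotype-by-risk-factor interactions and probe-polymorphism
#' artifacts, plus Gaussian noise.
#'
#' Planted effect tables (all optional, `NULL` means none):
#' \describe{
#'   \item{cis_effects / trans_effects}{data.frame with columns `gene`,
#'     `snp` and one of `beta` (effect per minor allele on the
#'     transformed-expression scale) or `r2` (targeted fraction of
#'     expression variance, converted to a beta via
#'     `beta^2 = r2 * var(other) / ((1 - r2) * var(genotype))`). SNPs in
#'     `cis_effects` are placed within 1 Mb of their gene; SNPs in
#'     `trans_effects` are placed on a different chromosome.}
#'   \item{rf_effects}{columns `gene`, `rf` (a covariate name such as
#'     "smoking", "bmi", "sex"), and `beta` or `r2` as above.}
#'   \item{interaction_effects}{columns `gene`, `snp`, `rf`, `beta`; the
#'     interaction predictor is the product of the centred genotype and
#'     centred risk factor.}
#'   \item{probe_artifacts}{columns `gene`, `snp`, `attenuation`:
#'     measured expression is lowered by `attenuation` per alternate
#'     allele, emulating weakened probe hybridization over a SNP in the
#'     probe sequence.}
#' }
#'
#' @param n_samples,n_snps,n_genes Cohort dimensions.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param maf_range Range the per-SNP minor allele frequencies are drawn
#'   from; must lie within (0.01, 0.5].
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param ld_rho Within-block latent correlation in [0, 1).
#' @param cis_effects,trans_effects,rf_effects,interaction_effects,probe_artifacts
#'   Planted effect tables, see Details.
#' @param noise_sd Residual SD of expression (transformed scale).
#' @param missing_rate Genotype missing-call rate (default 0).
#' @param seed Master seed; every sub-generator derives its own stream
#'   from it, so identical configs give bit-identical cohorts.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1490, n_snps = 1000, n_genes = 100,
                       chrom_lengths = c("1" = 2.4e8, "2" = 2.4e8,
                                         "3" = 2.0e8, "4" = 1.9e8),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_rho = 0.6,
                       cis_effects = NULL, trans_effects = NULL,
                       rf_effects = NULL, interaction_effects = NULL,
                       probe_artifacts = NULL,
                       noise_sd = 1, missing_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 2, n_snps >= 1, n_genes >= 1,
            length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 2e6))
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0.01 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within (0.01, 0.5]")
  stopifnot(ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1)

  check_effects <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns ", paste(cols, collapse = ", "))
    if ("beta" %in% names(df) || "r2" %in% names(df)) {
      if (is.null(df$beta)) df$beta <- NA_real_
      if (is.null(df$r2)) df$r2 <- NA_real_
    }
    df
  }
  cis_effects <- check_effects(cis_effects, c("gene", "snp"), "cis_effects")
  trans_effects <- check_effects(trans_effects, c("gene", "snp"), "trans_effects")
  rf_effects <- check_effects(rf_effects, c("gene", "rf"), "rf_effects")
  interaction_effects <- check_effects(interaction_effects,
                                       c("gene", "snp", "rf", "beta"),
                                       "interaction_effects")
  probe_artifacts <- check_effects(probe_artifacts,
                                   c("gene", "snp", "attenuation"),
                                   "probe_artifacts")

  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), chrom_lengths = chrom_lengths,
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, cis_effects = cis_effects,
    trans_effects = trans_effects, rf_effects = rf_effects,
    interaction_effects = interaction_effects,
    probe_artifacts = probe_artifacts, noise_sd = noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")

  ids <- sim_ids(cfg)
  for (df in list(cis_effects, trans_effects, probe_artifacts,
                  interaction_effects)) {
    if (is.null(df)) next
    if (!all(df$gene %in% ids$genes)) stop("planted gene id not in cohort")
    if (!all(df$snp %in% ids$snps)) stop("planted SNP id not in cohort")
  }
  if (!is.null(rf_effects) && !all(rf_effects$gene %in% ids$genes))
    stop("planted gene id not in cohort")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,", x$n_snps, "SNPs,",
      x$n_genes, "genes\n")
  cat(sprintf("  LD blocks of %d SNPs, rho = %.2f; MAF in [%.2f, %.2f]\n",
              x$ld_block_size, x$ld_rho, x$maf_range[1], x$maf_range[2]))
  n_eff <- function(d) if (is.null(d)) 0L else nrow(d)
  cat(sprintf("  planted: %d cis, %d trans, %d risk-factor, %d interaction, %d probe artifacts\n",
              n_eff(x$cis_effects), n_eff(x$trans_effects),
              n_eff(x$rf_effects), n_eff(x$interaction_effects),
              n_eff(x$probe_artifacts)))
  invisible(x)
}

# Identifier sets for a config.
sim_ids <- function(config) {
  list(samples = sprintf("S%04d", seq_len(config$n_samples)),
       snps = sprintf("rs%05d", seq_len(config$n_snps)),
       genes = sprintf("G%04d", seq_len(config$n_genes)))
}

# Deterministic genomic layout: gene intervals (with probe intervals) and
# SNP positions in LD blocks. Blocks carrying planted cis SNPs are placed
# within 1 Mb of their gene; blocks carrying planted trans SNPs are moved
# to a different chromosome than their gene.
sim_layout <- function(config) {
  ids <- sim_ids(config)
  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths
  set.seed(derive_seed(config$seed, "layout"))

  gene_chrom <- sample(chroms, config$n_genes, replace = TRUE,
                       prob = lens / sum(lens))
  gene_len <- round(runif(config$n_genes, 5e3, 2e5))
  gene_start <- vapply(seq_len(config$n_genes), function(i) {
    round(runif(1, 1e6, lens[gene_chrom[i]] - gene_len[i] - 1e6))
  }, numeric(1))
  probe_off <- round(runif(config$n_genes, 0, pmax(gene_len - 50, 0)))
  gene_meta <- data.frame(gene = ids$genes, chrom = gene_chrom,
                          start = gene_start, end = gene_start + gene_len,
                          probe_start = gene_start + probe_off,
                          probe_end = gene_start + probe_off + 49,
                          row.names = NULL)

  n_blocks <- ceiling(config$n_snps / config$ld_block_size)
  block_of <- rep(seq_len(n_blocks),
                  each = config$ld_block_size)[seq_len(config$n_snps)]
  block_chrom <- sample(chroms, n_blocks, replace = TRUE,
                        prob = lens / sum(lens))
  block_anchor <- vapply(seq_len(n_blocks), function(b) {
    round(runif(1, 1, lens[block_chrom[b]] - 1e6))
  }, numeric(1))

  # honour planted placements, whole LD block at a time
  place <- function(df, mode) {
    for (k in seq_len(nrow(df))) {
      b <- block_of[match(df$snp[k], ids$snps)]
      g <- match(df$gene[k], ids$genes)
      if (mode == "cis") {
        block_chrom[b] <<- gene_meta$chrom[g]
        block_anchor[b] <<- max(1, round(runif(
          1, gene_meta$start[g] - 5e5, gene_meta$end[g] + 4e5)))
      } else {
        if (block_chrom[b] == gene_meta$chrom[g]) {
          other <- setdiff(chroms, gene_meta$chrom[g])
          if (length(other) == 0)
            stop("trans effect needs at least two chromosomes")
          block_chrom[b] <<- sample(other, 1)
          block_anchor[b] <<- round(runif(1, 1, lens[block_chrom[b]] - 1e6))
        }
      }
    }
  }
  if (!is.null(config$cis_effects)) place(config$cis_effects, "cis")
  if (!is.null(config$trans_effects)) place(config$trans_effects, "trans")

  gaps <- matrix(round(runif(n_blocks * config$ld_block_size, 100, 5e3)),
                 nrow = n_blocks)
  pos <- numeric(config$n_snps)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    pos[idx] <- block_anchor[b] + cumsum(gaps[b, seq_along(idx)])
  }
  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  snp_meta <- data.frame(snp = ids$snps, chrom = block_chrom[block_of],
                         pos = pos, maf = maf, block = block_of,
                         row.names = NULL)

  # invariant check on planted placements
  if (!is.null(config$cis_effects)) {
    for (k in seq_len(nrow(config$cis_effects))) {
      s <- snp_meta[match(config$cis_effects$snp[k], snp_meta$snp), ]
      g <- gene_meta[match(config$cis_effects$gene[k], gene_meta$gene), ]
      if (s$chrom != g$chrom || s$pos < g$start - 1e6 || s$pos > g$end + 1e6)
        stop("internal error: planted cis SNP not within 1 Mb of its gene ",
             "(conflicting planted effects within one LD block?)")
    }
  }
  if (!is.null(config$trans_effects)) {
    for (k in seq_len(nrow(config$trans_effects))) {
      s <- snp_meta[match(config$trans_effects$snp[k], snp_meta$snp), ]
      g <- gene_meta[match(config$trans_effects$gene[k], gene_meta$gene), ]
      if (s$chrom == g$chrom)
        stop("conflicting planted effects: trans SNP landed on the gene's chromosome")
    }
  }
  list(gene_meta = gene_meta, snp_meta = snp_meta)
}
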