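test_that("simulated genotypes are HWE at their MAF and LD-free when rho=0", {
  cfg <- sim_config(n_samples = 1e5, n_snps = 40, n_genes = 2,
                    maf_range = c(0.5, 0.5), ld_block_size = 2,
                    ld_rho = 0, seed = 3)
  G <- sim_genotypes(cfg)
  freq <- apply(G$codes, 2, function(g) tabulate(g + 1L, 3) / length(g))
  # HWE at p = q = 0.5: (0.25, 0.5, 0.25) within 3 binomial SD
  for (j in 1:4) {
    expect_lt(abs(freq[1, j] - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
    expect_lt(abs(freq[2, j] - 0.50), 3 * sqrt(0.50 * 0.50 / 1e5))
  }
  # independence within blocks when rho = 0: mean within-block r2 < 2/n
  r2 <- vapply(seq(1, 39, by = 2), function(j)
    cor(G$codes[, j], G$codes[, j + 1])^2, numeric(1))
  expect_lt(mean(r2), 2 / 1e5)
})

test_that("HWE chi-square P-values are uniform across null SNPs", {
  cfg <- sim_config(n_samples = 2000, n_snps = 400, n_genes = 2,
                    ld_block_size = 1, ld_rho = 0, seed = 13)
  G <- sim_genotypes(cfg)
  p <- apply(G$codes, 2, function(g) hwe_test(tabulate(g + 1L, 3))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("block LD matches the frozen thresholded-copula oracle", {
  # oracle: 1e6-draw Monte Carlo of the latent-Gaussian copula with
  # rho = 0.95 and both MAFs 0.3 gives genotype-scale r2 = 0.6907
  cfg <- sim_config(n_samples = 5000, n_snps = 2, n_genes = 2,
                    maf_range = c(0.3, 0.3), ld_block_size = 2,
                    ld_rho = 0.95, seed = 17)
  G <- sim_genotypes(cfg)
  r2 <- cor(G$codes[, 1], G$codes[, 2])^2
  expect_equal(r2, 0.6907, tolerance = 0.05 / 0.6907)
  expect_equal(ld_r2(G, "rs00001", "rs00002"), r2)
})

test_that("simulation is deterministic given the seed and honours missingness", {
  cfg <- tiny_config(seed = 23, n_samples = 80)
  co1 <- sim_cohort(cfg)
  co2 <- sim_cohort(tiny_config(seed = 23, n_samples = 80))
  expect_identical(co1$genotypes$codes, co2$genotypes$codes)
  expect_identical(co1$expression$values, co2$expression$values)
  expect_identical(co1$covariates, co2$covariates)
  cfg_miss <- sim_config(n_samples = 500, n_snps = 50, n_genes = 2,
                         missing_rate = 0.05, seed = 29)
  G <- sim_genotypes(cfg_miss)
  expect_equal(mean(is.na(G$codes)), 0.05, tolerance = 0.3)
})

test_that("risk factors reproduce the reference distribution", {
  cfg <- sim_config(n_samples = 1e5, n_snps = 1, n_genes = 1, seed = 7)
  rfs <- sim_risk_factors(cfg)
  men <- rfs[rfs$sex == "male", ]
  women <- rfs[rfs$sex == "female", ]
  expect_equal(nrow(men) / 1e5, 760 / 1490, tolerance = 0.02)
  # male BMI mean within 3 SE, SD within 5%
  expect_lt(abs(mean(men$bmi) - 27.6), 3 * 3.9 / sqrt(nrow(men)))
  expect_lt(abs(sd(men$bmi) - 3.9) / 3.9, 0.05)
  # female smoking prevalence within 3 SE of 15.5%
  se <- sqrt(0.155 * 0.845 / nrow(women))
  expect_lt(abs(mean(women$smoking) - 0.155), 3 * se)
  expect_lt(abs(mean(women$hdl) - 69.2), 3 * 17.8 / sqrt(nrow(women)))
  expect_equal(rfs$sqrt_crp, sqrt(rfs$crp))
})

test_that("planted effects reach their target variance fractions", {
  cfg <- sim_config(
    n_samples = 1490, n_snps = 40, n_genes = 6, ld_block_size = 4,
    cis_effects = data.frame(gene = "G0001", snp = "rs00003", r2 = 0.25),
    rf_effects = data.frame(gene = "G0002", rf = "bmi", r2 = 0.1),
    seed = 41)
  co <- sim_cohort(cfg)
  led <- co$ledger$effects
  # sampling band for R2 = 0.25 at n = 1490 (~2 SD of the R2 estimator)
  cis <- led[led$type == "cis", ]
  expect_equal(cis$r2_realized, 0.25, tolerance = 0.04 / 0.25)
  g <- co$genotypes$codes[, "rs00003"]
  expect_equal(summary(lm(co$expression$values[, "G0001"] ~ g))$r.squared,
               cis$r2_realized, tolerance = 1e-10)
  rf <- led[led$type == "rf", ]
  expect_equal(rf$r2_realized, 0.1, tolerance = 0.4)
  # every planted effect appears exactly once in the ledger
  expect_equal(nrow(led), 2)
  expect_false(any(duplicated(led[, c("type", "gene", "snp", "rf")])))
})

test_that("noiseless single-effect expression is collinear with genotype", {
  cfg <- sim_config(
    n_samples = 200, n_snps = 10, n_genes = 2, ld_block_size = 2,
    cis_effects = data.frame(gene = "G0001", snp = "rs00001", beta = 1),
    noise_sd = 1e-12, seed = 43)
  co <- sim_cohort(cfg)
  g <- co$genotypes$codes[, "rs00001"]
  expect_gt(cor(co$expression$values[, "G0001"], g)^2, 1 - 1e-8)
})

test_that("over-committed variance fractions are rejected", {
  cfg <- sim_config(
    n_samples = 100, n_snps = 10, n_genes = 2,
    cis_effects = data.frame(gene = "G0001", snp = "rs00001", r2 = 0.6),
    rf_effects = data.frame(gene = "G0001", rf = "bmi", r2 = 0.5),
    seed = 44)
  G <- sim_genotypes(cfg)
  C <- sim_risk_factors(cfg)
  expect_error(sim_expression(G, C, cfg), ">= 1")
})

test_that("cis SNPs are placed within 1 Mb and trans SNPs on other chromosomes", {
  cfg <- tiny_config(seed = 47, n_samples = 50)
  G <- sim_genotypes(cfg)
  sm <- G$snp_meta
  layout_gene <- sim_cohort(cfg)$expression$gene_meta
  s <- sm[sm$snp == "rs00005", ]; g <- layout_gene[layout_gene$gene == "G0001", ]
  expect_equal(s$chrom, g$chrom)
  expect_true(s$pos >= g$start - 1e6 && s$pos <= g$end + 1e6)
  s2 <- sm[sm$snp == "rs00050", ]; g2 <- layout_gene[layout_gene$gene == "G0002", ]
  expect_false(s2$chrom == g2$chrom)
})

test_that("detection P-values follow the detected/undetected design", {
  cfg <- sim_config(n_samples = 200, n_snps = 2, n_genes = 1000, seed = 53)
  co <- sim_cohort(cfg, frac_undetected = 0.2)
  kept <- detection_filter(co$detection)
  # kept count within 3 binomial SD of the Bernoulli design
  expect_lt(abs(length(kept) - 800), 3 * sqrt(1000 * 0.2 * 0.8))
  expect_setequal(kept, setdiff(colnames(co$expression$values),
                                co$undetected))
  # boundary fractions
  d0 <- sim_detection_pvalues(co$expression, 0, seed = 1)
  expect_equal(length(detection_filter(d0$detection)), 1000)
  d1 <- sim_detection_pvalues(co$expression, 1, seed = 1)
  expect_equal(length(detection_filter(d1$detection)), 0)
})

test_that("plaque simulation recovers the smoking link and the null is flat", {
  cfg <- sim_config(n_samples = 5e4, n_snps = 2, n_genes = 2, seed = 59)
  co <- sim_cohort(cfg)
  pl <- sim_plaques(co$covariates, co$expression,
                    link = list(intercept = log(0.8), smoking = 0.7),
                    seed = 61)
  fit <- glm(pl ~ co$covariates$smoking, family = poisson())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 0.7), 3 * est["Std. Error"])
  # zero link: regression P uniform over seeds
  p0 <- vapply(1:40, function(s) {
    pl0 <- sim_plaques(co$covariates, co$expression,
                       link = list(intercept = log(0.5)), seed = s)
    summary(lm(pl0 ~ co$covariates$smoking))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)
})
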