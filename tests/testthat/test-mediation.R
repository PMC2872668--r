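# Cohort with a full mediation chain: SNP -> gene expression -> phenotype.
# Each leg is strong at n = 800 so single-seed verdicts are stable.
mediation_cohort <- function(seed, sever = c("none", "snp_expr",
                                             "expr_pheno")) {
  sever <- match.arg(sever)
  cfg <- sim_config(
    n_samples = 800, n_snps = 20, n_genes = 4, ld_block_size = 4,
    cis_effects = if (sever == "snp_expr") NULL else
      data.frame(gene = "G0001", snp = "rs00002", r2 = 0.15),
    seed = seed)
  co <- sim_cohort(cfg)
  set.seed(derive_seed_for_test(seed))
  e <- co$expression$values[, "G0001"]
  if (sever == "expr_pheno") {
    co$covariates$hdl <- 55 + rnorm(800, sd = 14)
  } else {
    # phenotype driven by the expression trait (plus noise)
    co$covariates$hdl <- 55 + 6 * (e - mean(e)) / sd(e) + rnorm(800, sd = 10)
  }
  co
}
derive_seed_for_test <- function(seed) (seed * 7919) %% 100000

test_that("triangle verdict is compatible for a full mediation chain", {
  co <- mediation_cohort(301)
  res <- triangle_test(co$genotypes, co$expression, co$covariates,
                       lead_snp = "rs00002", phenotype = "hdl",
                       genes = c("G0001", "G0002"))
  expect_equal(res$verdict, "compatible")
  expect_equal(res$tag$snp, "rs00002")
  g <- res$genes
  expect_true(g$compatible[g$gene == "G0001"])
  expect_false(g$compatible[g$gene == "G0002"])
  # legs agree with explicit lm oracles
  d <- data.frame(hdl = co$covariates$hdl,
                  g = as.numeric(co$genotypes$codes[, "rs00002"]),
                  age = co$covariates$age,
                  sex = monoqtl:::sex_code(co$covariates$sex),
                  bmi = co$covariates$bmi)
  p_oracle <- summary(lm(hdl ~ g + age + sex + bmi, d))$coefficients["g", 4]
  expect_equal(g$p_snp_pheno[1], p_oracle, tolerance = 1e-10)
})

test_that("severing either leg breaks compatibility", {
  co1 <- mediation_cohort(307, sever = "snp_expr")
  r1 <- triangle_test(co1$genotypes, co1$expression, co1$covariates,
                      "rs00002", "hdl", "G0001")
  expect_true(r1$verdict %in% c("untestable", "incompatible"))
  expect_false(isTRUE(r1$genes$compatible[1]))
  co2 <- mediation_cohort(311, sever = "expr_pheno")
  r2 <- triangle_test(co2$genotypes, co2$expression, co2$covariates,
                      "rs00002", "hdl", "G0001")
  expect_equal(r2$verdict, "incompatible")
})

test_that("triangle verdict is invariant to flipping the coded allele", {
  co <- mediation_cohort(313)
  res <- triangle_test(co$genotypes, co$expression, co$covariates,
                       "rs00002", "hdl", "G0001")
  flipped <- co$genotypes
  flipped$codes[, "rs00002"] <- 2 - flipped$codes[, "rs00002"]
  res_f <- triangle_test(flipped, co$expression, co$covariates,
                         "rs00002", "hdl", "G0001")
  expect_equal(res_f$verdict, res$verdict)
  expect_equal(res_f$genes$beta_snp_expr, -res$genes$beta_snp_expr,
               tolerance = 1e-10)
})

test_that("no adequate proxy yields an untestable locus", {
  co <- mediation_cohort(317)
  set.seed(1)
  weak <- rbinom(800, 2, 0.3)  # unrelated to anything on the panel
  res <- triangle_test(co$genotypes, co$expression, co$covariates,
                       lead_snp = "rsOFF", phenotype = "hdl",
                       genes = "G0001",
                       lead_chrom = co$genotypes$snp_meta$chrom[2],
                       lead_pos = co$genotypes$snp_meta$pos[2],
                       lead_codes = weak)
  expect_equal(res$verdict, "untestable")
})

test_that("attenuation verdict distinguishes mediated from direct effects", {
  # fully mediated design: smoking -> 4 genes -> plaques, direct effect
  # 0; modest log-scale coefficients keep the count model in the
  # near-linear regime the linear adjustment assumes
  mediated <- function(seed) {
    genes <- sprintf("G%04d", 1:4)
    cfg <- sim_config(
      n_samples = 1490, n_snps = 4, n_genes = 5,
      rf_effects = data.frame(gene = genes, rf = "smoking", r2 = 0.2),
      seed = seed)
    co <- sim_cohort(cfg, plaque_link = list(
      intercept = log(0.6), smoking = 0,
      genes = setNames(rep(0.08, 4), genes)))
    attenuation_test(co$covariates$plaque_count, "smoking", genes,
                     co$covariates, co$expression)
  }
  runs <- lapply(330 + 1:12, mediated)
  expect_true(all(vapply(runs, function(r) r$p_rf_a < 0.05, logical(1))))
  expect_gte(mean(vapply(runs, `[[`, logical(1), "attenuated")), 0.8)
  # direct-effect-only: adjustment cannot explain the association away
  co2 <- sim_cohort(sim_config(n_samples = 1000, n_snps = 4, n_genes = 4,
                               seed = 337),
                    plaque_link = list(intercept = log(0.6),
                                       smoking = 0.9))
  dir <- attenuation_test(co2$covariates$plaque_count, "smoking",
                          c("G0001", "G0002"), co2$covariates,
                          co2$expression)
  expect_false(dir$attenuated)
  expect_lt(dir$p_rf_b, 0.05)
  # no mediators: model B equals model A, never attenuated
  none <- attenuation_test(co2$covariates$plaque_count, "smoking",
                           character(), co2$covariates, co2$expression)
  expect_false(none$attenuated)
  expect_equal(none$p_rf_a, none$p_rf_b)
})

test_that("collinear mediators are dropped with a warning", {
  cfg <- sim_config(n_samples = 300, n_snps = 4, n_genes = 3, seed = 347)
  co <- sim_cohort(cfg, plaque_link = list(intercept = log(0.5),
                                           smoking = 0.5))
  co$expression$values[, "G0002"] <- 2 * co$expression$values[, "G0001"]
  expect_warning(
    res <- attenuation_test(co$covariates$plaque_count, "smoking",
                            c("G0001", "G0002"), co$covariates,
                            co$expression),
    "collinear")
  expect_equal(res$dropped, "G0002")
})

test_that("eSNP-outcome tests are null-calibrated and detect planted effects", {
  cfg <- sim_config(n_samples = 1000, n_snps = 20, n_genes = 2,
                    ld_block_size = 4, seed = 349)
  co <- sim_cohort(cfg)
  # null: no SNP-outcome link
  out_null <- rpois(1000, 0.6)
  res <- esnp_outcome_test(co$genotypes, out_null, co$covariates,
                           sprintf("rs%05d", 1:10))
  expect_true(all(res$p_bonf > 0.05))
  expect_equal(res$p_bonf, pmin(res$p * 10, 1))
  # planted: outcome depends on one SNP's dosage
  g <- co$genotypes$codes[, "rs00003"]
  set.seed(5)
  out_eff <- rpois(1000, exp(log(0.5) + 0.5 * g))
  res2 <- esnp_outcome_test(co$genotypes, out_eff, co$covariates,
                            sprintf("rs%05d", 1:10))
  expect_lt(res2$p_bonf[res2$snp == "rs00003"], 0.05)
  # empty list: empty table
  expect_equal(nrow(esnp_outcome_test(co$genotypes, out_null,
                                      co$covariates, character())), 0)
})
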