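test_that("risk-factor scan coefficients match the lm oracle", {
  cfg <- sim_config(
    n_samples = 400, n_snps = 10, n_genes = 8,
    rf_effects = data.frame(gene = "G0001", rf = "smoking", r2 = 0.15),
    seed = 101)
  co <- sim_cohort(cfg)
  res <- rf_assoc_scan(co$expression, co$covariates, rfs = "smoking",
                       threshold = 1e-4)
  hit <- res[res$gene == "G0001", ]
  expect_true(hit$significant)
  # oracle: full lm fit with the same adjustment scheme
  fit <- lm(co$expression$values[, "G0001"] ~ smoking + age +
              I(sex == "female"), data = co$covariates)
  cf <- summary(fit)$coefficients["smoking", ]
  expect_equal(hit$beta, unname(cf["Estimate"]), tolerance = 1e-10)
  expect_equal(hit$t, unname(cf["t value"]), tolerance = 1e-10)
  expect_equal(hit$p, unname(cf["Pr(>|t|)"]), tolerance = 1e-10)
  # planted coefficient recovered within 2 SE
  truth <- co$ledger$effects$beta[co$ledger$effects$gene == "G0001"]
  expect_lt(abs(hit$beta - truth) / cf["Std. Error"], 3)
})

test_that("null risk-factor scan is calibrated and constants give P=1", {
  cfg <- sim_config(n_samples = 300, n_snps = 2, n_genes = 400, seed = 103)
  co <- sim_cohort(cfg)
  covs <- co$covariates
  set.seed(1)
  covs$bmi <- sample(covs$bmi)  # permutation breaks any structure
  res <- rf_assoc_scan(co$expression, covs, rfs = "bmi", threshold = 0.05)
  expect_equal(mean(res$significant), 0.05, tolerance = 0.5)
  # constant expression trait
  E2 <- co$expression
  E2$values[, 1] <- 5
  res2 <- rf_assoc_scan(E2, covs, rfs = "bmi", threshold = 0.05)
  expect_equal(res2$beta[1], 0)
  expect_equal(res2$p[1], 1)
})

test_that("planted smoking gene is a risk-factor hit but not an eQTL", {
  cfg <- sim_config(
    n_samples = 500, n_snps = 60, n_genes = 6, ld_block_size = 6,
    rf_effects = data.frame(gene = "G0004", rf = "smoking", r2 = 0.12),
    seed = 107)
  co <- sim_cohort(cfg)
  rf <- rf_assoc_scan(co$expression, co$covariates, rfs = "smoking",
                      threshold = 1e-4)
  expect_true(rf$significant[rf$gene == "G0004"])
  scan <- genome_scan(co$expression, co$genotypes, co$covariates,
                      store_below = 1e-5)
  expect_false("G0004" %in% scan$gene)
})

test_that("enrichment odds ratios and Woolf CIs reproduce the reference table", {
  # smoking: 294 risk-factor traits of which 126 cis, against the
  # 12,808-trait background with 2,477 cis traits
  sm <- enrichment_or(126, 294 - 126, 2477 - 126,
                      12808 - 294 - (2477 - 126))
  expect_equal(round(sm$or, 2), 3.24)
  expect_equal(round(sm$ci, 2), c(2.56, 4.10))
  ge <- enrichment_or(230, 577, 2247, 9754)
  expect_equal(round(ge$or, 2), 1.73)
  # CI bounds within one unit of the printed 2-decimal precision
  expect_equal(ge$ci, c(1.47, 2.03), tolerance = 0.01)
  crp <- enrichment_or(116, 328 - 116, 2477 - 116,
                       12808 - 328 - (2477 - 116))
  expect_equal(crp$or, 2.34, tolerance = 0.01)
  expect_equal(round(crp$ci, 2), c(1.86, 2.95))
  expect_equal(enrichment_or(10, 10, 10, 10)$or, 1.0)
})

test_that("odds ratio symmetries and zero-cell handling hold", {
  e <- enrichment_or(12, 34, 56, 78)
  # swapping both rows and both columns leaves the OR unchanged,
  # as does transposing the table
  expect_equal(enrichment_or(78, 56, 34, 12)$or, e$or)
  expect_equal(enrichment_or(12, 56, 34, 78)$or, e$or)
  # swapping one margin (columns) inverts it
  expect_equal(enrichment_or(34, 12, 78, 56)$or, 1 / e$or,
               tolerance = 1e-12)
  z <- enrichment_or(0, 5, 5, 5)
  expect_true(all(is.na(z$ci)))
  zc <- enrichment_or(0, 5, 5, 5, correction = TRUE)
  expect_false(anyNA(zc$ci))
})

test_that("binomial enrichment matches a direct-summation oracle", {
  p0 <- 35.8 / 465
  oracle <- sum(dbinom(69:465, 465, p0))
  expect_equal(binomial_enrichment(69, 35.8, 465), oracle)
  # observed at expectation: corrected P near 1; extreme tail tiny
  expect_gt(binomial_enrichment(36, 35.8, 465), 0.4)
  expect_lt(binomial_enrichment(465, 1, 465), 1e-10)
  # Bonferroni factor and cap
  expect_equal(binomial_enrichment(69, 35.8, 465, n_categories = 3),
               min(3 * oracle, 1))
  expect_equal(binomial_enrichment(36, 35.8, 465, n_categories = 100), 1)
})

test_that("interaction scan detects a planted interaction and matches lm", {
  cfg <- sim_config(
    n_samples = 1490, n_snps = 20, n_genes = 4, ld_block_size = 4,
    cis_effects = data.frame(gene = "G0001", snp = "rs00002", r2 = 0.1),
    rf_effects = data.frame(gene = "G0001", rf = "smoking", r2 = 0.05),
    interaction_effects = data.frame(gene = "G0001", snp = "rs00002",
                                     rf = "smoking", beta = 0.6),
    seed = 109)
  co <- sim_cohort(cfg)
  pairs <- data.frame(gene = c("G0001", "G0002"),
                      snp = c("rs00002", "rs00010"),
                      rf = "smoking")
  res <- interaction_scan(co$expression, co$genotypes, co$covariates,
                          pairs)
  expect_lt(res$q[1], 0.05)
  expect_gt(res$p[2], res$p[1])
  # oracle: explicit lm with the same model
  d <- data.frame(e = co$expression$values[, "G0001"],
                  g = co$genotypes$codes[, "rs00002"],
                  x = co$covariates$smoking,
                  age = co$covariates$age,
                  sex = monoqtl:::sex_code(co$covariates$sex))
  cf <- summary(lm(e ~ g + x + age + sex + g:x, d))$coefficients
  expect_equal(res$p[1], cf["g:x", 4], tolerance = 1e-10)
  # single pair: q equals the raw P
  r1 <- interaction_scan(co$expression, co$genotypes, co$covariates,
                         pairs[1, ])
  expect_equal(r1$q, r1$p)
})

test_that("purely additive simulations yield flat interaction q-values", {
  # no planted interactions: the BH-minimum should rarely dip below 0.05
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(
      n_samples = 400, n_snps = 30, n_genes = 10, ld_block_size = 3,
      cis_effects = data.frame(gene = sprintf("G%04d", 1:5),
                               snp = sprintf("rs%05d", c(1, 4, 7, 10, 13)),
                               r2 = 0.1),
      rf_effects = data.frame(gene = sprintf("G%04d", 1:5),
                              rf = "smoking", r2 = 0.05),
      seed = 1000 + s)
    co <- sim_cohort(cfg)
    pairs <- data.frame(gene = sprintf("G%04d", 1:5),
                        snp = sprintf("rs%05d", c(1, 4, 7, 10, 13)),
                        rf = "smoking")
    res <- interaction_scan(co$expression, co$genotypes, co$covariates,
                            pairs)
    min(res$q) < 0.05
  }, logical(1))
  expect_lte(sum(hits), 1)
})
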