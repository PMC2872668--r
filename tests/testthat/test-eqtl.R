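test_that("genotype grouping merges rare minor homozygotes at the 30 boundary", {
  mk <- function(n0, n1, n2) c(rep(0, n0), rep(1, n1), rep(2, n2))
  g3 <- group_genotypes(mk(1000, 400, 30))
  expect_equal(g3$n_groups, 3)
  g2 <- group_genotypes(mk(1000, 400, 29))
  expect_equal(g2$n_groups, 2)
  expect_equal(as.vector(table(g2$labels)), c(1000L, 429L))
  expect_equal(group_genotypes(mk(1000, 490, 0))$n_groups, 2)
  # rare heterozygotes: merge the two smallest groups
  gh <- group_genotypes(mk(1000, 20, 40))
  expect_equal(gh$n_groups, 2)
  expect_equal(sort(as.vector(table(gh$labels))), c(60L, 1000L))
  # single group after merging is untestable
  expect_false(group_genotypes(mk(1000, 0, 0))$testable)
})

test_that("one-way ANOVA matches the hand example and the lm oracle", {
  expr <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(1:3, each = 3)
  a <- anova_assoc(expr, grp)
  expect_equal(a$f, 3)
  expect_equal(a$r2, 0.5)
  expect_equal(a$p, 0.125)
  # exact F(2,6) survival: (1 + F/3)^-3
  expect_equal(a$p, (1 + 3 / 3)^-3)

  # oracle cross-check on random fixtures against stats::lm / anova
  set.seed(5)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    g <- sample(1:3, n, replace = TRUE)
    y <- rnorm(n) + 0.3 * g
    if (length(unique(g)) < 2) next
    ours <- anova_assoc(y, g)
    fit <- anova(lm(y ~ factor(g)))
    expect_equal(ours$f, fit[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p, fit[1, "Pr(>F)"], tolerance = 1e-10)
    expect_equal(ours$r2, summary(lm(y ~ factor(g)))$r.squared,
                 tolerance = 1e-10)
    # 2-group ANOVA F equals the squared two-sample t statistic
    g2 <- as.integer(g >= 2)
    if (length(unique(g2)) == 2) {
      tt <- t.test(y[g2 == 0], y[g2 == 1], var.equal = TRUE)
      expect_equal(anova_assoc(y, g2)$f, unname(tt$statistic)^2,
                   tolerance = 1e-10)
    }
  }
})

test_that("ANOVA R2 is affine-invariant and degenerate input gives P=1", {
  set.seed(8)
  y <- rnorm(50); g <- sample(1:3, 50, replace = TRUE)
  expect_equal(anova_assoc(y, g)$r2, anova_assoc(3 - 2 * y, g)$r2)
  d <- anova_assoc(rep(1, 50), g)
  expect_equal(d$p, 1)
  expect_equal(d$r2, 0)
})

test_that("Kruskal-Wallis confirmation matches the hand rank computation", {
  expect_equal(kw_confirm(c(1, 2, 3, 4), c(1, 1, 2, 2)),
               pchisq(2.4, 1, lower.tail = FALSE))
  expect_equal(kw_confirm(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0.1213353,
               tolerance = 1e-6)
  expect_equal(kw_confirm(rep(2, 10), rep(1:2, 5)), 1)
})

test_that("Fisher combination has the chi-square(4) closed form", {
  # e^(-X/2) (1 + X/2) for 4 df
  cf <- function(p1, p2) {
    x <- -2 * (log(p1) + log(p2)); exp(-x / 2) * (1 + x / 2)
  }
  expect_equal(fisher_combine(c(0.5, 0.5)), cf(0.5, 0.5))
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(1e-8, 1)), cf(1e-8, 1))
  expect_equal(fisher_combine(c(1e-8, 1)), 1.942068e-7, tolerance = 1e-6)
})

test_that("X-chromosome association combines the sexes by Fisher's method", {
  set.seed(21)
  n <- 400
  sex <- rep(c("male", "female"), each = n / 2)
  # male hemizygotes on 0/2 coding, females 0/1/2
  codes <- ifelse(sex == "male", sample(c(0, 2), n, replace = TRUE),
                  rbinom(n, 2, 0.4))
  y <- rnorm(n) + 0.35 * codes
  res <- chrx_assoc(y, codes, sex)
  expect_equal(res$flag, "combined")
  male <- sex == "male"
  pm <- anova_assoc(y[male], group_genotypes(codes[male])$labels)$p
  pf_ <- anova_assoc(y[!male], group_genotypes(codes[!male])$labels)$p
  expect_equal(res$p, fisher_combine(c(pm, pf_)))
  # one sex untestable falls back to the other, flagged
  codes2 <- codes; codes2[male] <- 0
  res2 <- chrx_assoc(y, codes2, sex)
  expect_equal(res2$flag, "female_only")
  expect_equal(res2$p, res2$p_female)
})

test_that("genome scan recovers planted effects and stores below threshold", {
  cfg <- tiny_config(seed = 31, n_samples = 500)
  co <- sim_cohort(cfg)
  scan <- genome_scan(co$expression, co$genotypes, co$covariates,
                      store_below = 1e-5, study_wise = 1e-8)
  scan <- monoqtl:::annotate_cis_trans(scan)
  # planted cis effect (r2 0.2 at n=500) is found on the right gene
  hit_cis <- scan[scan$gene == "G0001" & scan$snp == "rs00005", ]
  expect_equal(nrow(hit_cis), 1)
  expect_true(hit_cis$study_wise)
  expect_equal(hit_cis$cis_trans, "cis")
  expect_equal(hit_cis$R2, 0.2, tolerance = 0.08)
  hit_trans <- scan[scan$gene == "G0002" & scan$snp == "rs00050", ]
  expect_equal(hit_trans$cis_trans, "trans")
  # stored records all below the storage threshold, sorted by gene then P
  expect_true(all(scan$p_anova < 1e-5))
  expect_false(is.unsorted(scan$gene))
  # recomputing a stored record from scratch reproduces it
  g <- group_genotypes(co$genotypes$codes[, hit_cis$snp])
  a <- anova_assoc(co$expression$values[, hit_cis$gene], g$labels)
  expect_equal(a$p, hit_cis$p_anova, tolerance = 1e-12)
  expect_equal(a$r2, hit_cis$R2, tolerance = 1e-12)
})

test_that("scan on misaligned or empty inputs fails early / returns empty", {
  cfg <- tiny_config(seed = 32, n_samples = 60)
  co <- sim_cohort(cfg)
  shuffled <- co$genotypes
  shuffled$codes <- shuffled$codes[rev(seq_len(nrow(shuffled$codes))), ]
  expect_error(genome_scan(co$expression, shuffled, co$covariates),
               "sample ids")
  empty <- genotype_matrix(
    matrix(integer(), 60, 0,
           dimnames = list(rownames(co$genotypes$codes), NULL)),
    data.frame(snp = character(), chrom = character(), pos = numeric()))
  expect_equal(nrow(genome_scan(co$expression, empty, co$covariates)), 0)
})

test_that("X SNPs in the scan are routed through the sex-stratified test", {
  set.seed(77)
  n <- 300
  sex <- rep(c("male", "female"), length.out = n)
  codes <- cbind(rsX1 = ifelse(sex == "male",
                               sample(c(0, 2), n, replace = TRUE),
                               rbinom(n, 2, 0.3)))
  rownames(codes) <- sprintf("S%04d", 1:n)
  G <- genotype_matrix(codes, data.frame(snp = "rsX1", chrom = "X",
                                         pos = 5e6))
  y <- matrix(rnorm(n) + 0.8 * codes[, 1], n, 1,
              dimnames = list(rownames(codes), "GX"))
  E <- expression_matrix(y, data.frame(gene = "GX", chrom = "X",
                                       start = 4.5e6, end = 4.6e6))
  covs <- data.frame(sex = sex)
  scan <- genome_scan(E, G, covs, store_below = 1e-3, study_wise = 1e-8)
  expect_equal(nrow(scan), 1)
  expect_true(scan$combined_x)
  oracle <- chrx_assoc(y[, 1], codes[, 1], sex)
  expect_equal(scan$p_anova, oracle$p)
  expect_error(genome_scan(E, G, covariates = NULL), "sex")
})

test_that("an adversarial outlier hit passes ANOVA but fails the KW filter", {
  # heavy outliers inflate the ANOVA F; the rank test is unimpressed
  n <- 600
  codes <- rep(c(0, 1, 2), times = c(400, 160, 40))
  y <- rnorm(n, sd = 0.05)
  y[codes == 2][1:6] <- 400   # six extreme outliers in the minor group
  g <- group_genotypes(codes)
  a <- anova_assoc(y, g$labels)
  kw <- kw_confirm(y, g$labels)
  expect_lt(a$p, 5.78e-12)
  expect_gt(kw, 1e-10)
})
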