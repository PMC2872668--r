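# --- covariate adjustment schemes -------------------------------------

#' Default covariate adjustment schemes
#'
#' Which covariates each risk-factor association is adjusted for:
#' age is adjusted for sex; BMI, smoking and sqrt-CRP for age and sex;
#' the lipids and blood pressures additionally for BMI; sex (gender)
#' for nothing.
#'
#' @return Named list mapping risk factor to character vector of
#'   covariates.
#' @export
default_schemes <- function() {
  list(sex = character(),
       age = "sex",
       bmi = c("age", "sex"),
       smoking = c("age", "sex"),
       sqrt_crp = c("age", "sex"),
       hdl = c("age", "sex", "bmi"),
       ldl = c("age", "sex", "bmi"),
       tg = c("age", "sex", "bmi"),
       sbp = c("age", "sex", "bmi"),
       dbp = c("age", "sex", "bmi"))
}

# Numeric value of a risk factor / covariate column. Sex uses the
# female = 1, male = 0 coding so positive coefficients mean higher in
# women.
rf_value <- function(covariates, rf) {
  if (rf %in% c("sex", "gender")) return(sex_code(covariates$sex))
  if (!rf %in% names(covariates)) stop("unknown risk factor: ", rf)
  as.numeric(covariates[[rf]])
}

# Covariate design matrix (with intercept) for a scheme entry.
scheme_matrix <- function(covariates, covs) {
  Z <- matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in covs) Z <- cbind(Z, rf_value(covariates, v))
  colnames(Z) <- c("(Intercept)", covs)
  Z
}

# Association of every column of Y with x, adjusted for Z (which must
# include the intercept): residualize both on Z, then the partial
# correlation t-test. Algebraically identical to the x coefficient of
# lm(y ~ x + Z) for each column. Columns with (residual) zero variance
# get beta 0, P 1.
partial_assoc <- function(Y, x, Z) {
  n <- length(x)
  stopifnot(nrow(Y) == n, nrow(Z) == n)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("collinear covariates")
  rx <- qr.resid(qz, x)
  RY <- qr.resid(qz, Y)
  ssx <- sum(rx^2)
  if (ssx <= 0) stop("risk factor collinear with covariates")
  ssy <- colSums(RY^2)
  # a column that is constant (or fully explained by the covariates)
  # carries no testable variance; guard against rounding residue
  vy <- colSums(sweep(Y, 2, colMeans(Y))^2)
  degenerate <- ssy <= 0 | vy <= 1e-20 | ssy <= 1e-14 * vy
  cross <- as.vector(crossprod(RY, rx))
  beta <- cross / ssx
  df <- n - ncol(Z) - 1
  r <- ifelse(!degenerate, cross / sqrt(ssx * pmax(ssy, 1e-300)), 0)
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[degenerate] <- 1; beta[degenerate] <- 0; t[degenerate] <- 0
  data.frame(gene = colnames(Y), beta = beta, t = t, p = p,
             row.names = NULL)
}

#' Expression-by-risk-factor association scan
#'
#' Linear regression of each expression trait on each risk factor with
#' the factor's covariate adjustment scheme
#' (`expression ~ risk factor + covariates`); reports the risk-factor
#' coefficient, t statistic and P-value, and flags study-wise
#' significance at `threshold` (default 3.9e-7, Bonferroni for 10 risk
#' factors x ~12.8k expressions). Samples with incomplete covariates
#' are dropped per risk factor. Collinear covariate schemes are skipped
#' with a reason.
#'
#' @param expr An [expression_matrix()] or samples-by-genes matrix.
#' @param covariates Covariate table (see [prepare_covariates()]).
#' @param rfs Risk factors to test (default: all in the scheme list
#'   present in the table).
#' @param schemes Adjustment schemes, see [default_schemes()].
#' @param threshold Study-wise significance threshold.
#' @return data.frame: gene, rf, n, beta, t, p, significant; skipped
#'   risk factors recorded in `attr(, "skipped")`.
#' @export
rf_assoc_scan <- function(expr, covariates, rfs = NULL,
                          schemes = default_schemes(),
                          threshold = 3.9e-7) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (is.null(rfs))
    rfs <- intersect(names(schemes),
                     c(names(covariates), "sex", "sqrt_crp"))
  out <- list(); skipped <- character()
  for (rf in rfs) {
    covs <- schemes[[rf]]
    if (is.null(covs)) covs <- c("age", "sex")
    x_all <- rf_value(covariates, rf)
    Z_all <- scheme_matrix(covariates, covs)
    ok <- complete.cases(cbind(x_all, Z_all))
    res <- tryCatch(
      partial_assoc(values[ok, , drop = FALSE], x_all[ok],
                    Z_all[ok, , drop = FALSE]),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, setNames(conditionMessage(res), rf))
      next
    }
    res$rf <- rf
    res$n <- sum(ok)
    out[[rf]] <- res
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), beta = numeric(), t = numeric(),
               p = numeric(), rf = character(), n = integer())
  out$significant <- out$p < threshold
  rownames(out) <- NULL
  out <- out[, c("gene", "rf", "n", "beta", "t", "p", "significant")]
  attr(out, "skipped") <- skipped
  attr(out, "threshold") <- threshold
  out
}

# --- enrichment --------------------------------------------------------

#' Odds ratio with Woolf confidence interval
#'
#' For the 2x2 table (a, b) / (c, d) — typically: risk-factor-associated
#' traits with / without a cis eSNP versus other traits with / without —
#' the odds ratio ad/bc with the Woolf (log-OR normal approximation)
#' confidence interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`,
#' no continuity correction unless requested.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @param correction Add 0.5 to every cell (needed when a cell is 0).
#' @return List of class `enrichment_result`: `or`, `ci` (low, high),
#'   `cells`.
#' @export
enrichment_or <- function(a, b, c, d, conf_level = 0.95,
                          correction = FALSE) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  cells <- c(a = a, b = b, c = c, d = d)
  if (correction) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (any(c(a, b, c, d) == 0)) {
    or <- if (b * c == 0) NA_real_ else (a * d) / (b * c)
    return(structure(list(or = or, ci = c(NA_real_, NA_real_),
                          cells = cells), class = "enrichment_result"))
  }
  or <- (a * d) / (b * c)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  structure(list(or = or, ci = ci, cells = cells),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f)\n", x$or, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Binomial category-enrichment P-value
#'
#' One-sided binomial tail for observing at least `observed` genes of a
#' functional category in a list drawn from a background where
#' `expected` are expected: P(X >= observed) with
#' X ~ Binomial(n_genes, expected / n_genes), Bonferroni-multiplied by
#' the number of categories tested and capped at 1.
#'
#' @param observed Observed category count in the list.
#' @param expected Expected count under the background.
#' @param n_genes Size of the gene list.
#' @param n_categories Number of categories tested (Bonferroni factor).
#' @return Corrected P-value.
#' @export
binomial_enrichment <- function(observed, expected, n_genes,
                                n_categories = 1) {
  stopifnot(expected > 0, observed >= 0, observed <= n_genes,
            n_categories >= 1)
  p0 <- expected / n_genes
  stopifnot(p0 < 1)
  p <- pbinom(observed - 1, n_genes, p0, lower.tail = FALSE)
  min(p * n_categories, 1)
}

# --- interaction -------------------------------------------------------

#' SNP-by-risk-factor interaction scan
#'
#' For each (gene, SNP, risk factor) triple, fits
#' `expression ~ SNP + RF + SNP:RF + scheme covariates` and tests the
#' interaction coefficient; P-values are Benjamini-Hochberg adjusted
#' across the tested pairs. The SNP enters additively (0/1/2), or on a
#' merged 0/1 coding when minor homozygotes are rare (see
#' [group_genotypes()]).
#'
#' @param expr An [expression_matrix()] or samples-by-genes matrix.
#' @param geno A [genotype_matrix()].
#' @param covariates Covariate table.
#' @param pairs data.frame with columns `gene`, `snp`, `rf`.
#' @param schemes Adjustment schemes (see [default_schemes()]).
#' @param min_homozygotes Group-merging threshold (30).
#' @return data.frame: gene, snp, rf, n, beta_interaction, t, p, q.
#' @export
interaction_scan <- function(expr, geno, covariates, pairs,
                             schemes = default_schemes(),
                             min_homozygotes = 30) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  stopifnot(all(c("gene", "snp", "rf") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    gene <- pairs$gene[i]; snp <- pairs$snp[i]; rf <- pairs$rf[i]
    if (!gene %in% colnames(values)) stop("unknown gene: ", gene)
    if (!snp %in% colnames(geno$codes)) stop("unknown SNP: ", snp)
    g_raw <- geno$codes[, snp]
    grp <- group_genotypes(g_raw, min_homozygotes)
    g <- if (grp$n_groups == 2) as.numeric(grp$labels - 1L) else
      as.numeric(g_raw)
    x <- rf_value(covariates, rf)
    covs <- schemes[[rf]]; if (is.null(covs)) covs <- c("age", "sex")
    Z <- scheme_matrix(covariates, covs)[, -1, drop = FALSE]
    e <- values[, gene]
    dat <- data.frame(e = e, g = g, x = x)
    if (ncol(Z)) dat <- cbind(dat, as.data.frame(Z))
    dat <- dat[complete.cases(dat), , drop = FALSE]
    fit_int <- lm(e ~ . + g:x, data = dat)
    cf <- summary(fit_int)$coefficients
    irow <- grep("^g:x$|^x:g$", rownames(cf))
    if (length(irow) != 1 || anyNA(coef(fit_int)))
      return(data.frame(gene = gene, snp = snp, rf = rf, n = nrow(dat),
                        beta_interaction = NA_real_, t = NA_real_,
                        p = NA_real_))
    data.frame(gene = gene, snp = snp, rf = rf, n = nrow(dat),
               beta_interaction = cf[irow, 1], t = cf[irow, 3],
               p = cf[irow, 4])
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
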