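# Fit y ~ x + covariates and return the x coefficient, t and P.
adjusted_assoc <- function(y, x, Z) {
  ok <- complete.cases(cbind(y, x, Z))
  res <- partial_assoc(matrix(y[ok], ncol = 1,
                              dimnames = list(NULL, "y")),
                       x[ok], Z[ok, , drop = FALSE])
  list(beta = res$beta, t = res$t, p = res$p, n = sum(ok))
}

#' Mediation-compatibility triangle test for a GWAS locus
#'
#' Tests whether a GWAS association between a locus and a phenotype is
#' compatible with mediation by local gene expression. Three
#' covariate-adjusted regressions are run with the lead SNP (or its
#' best tag SNP on the panel, via [proxy_search()]): SNP on phenotype,
#' SNP on each candidate gene expression, and expression on phenotype.
#' A gene is mediation-compatible when all three P-values pass their
#' thresholds and the signs cohere:
#' `sign(SNP->expr) * sign(expr->pheno) = sign(SNP->pheno)`. The locus
#' verdict is "compatible" if any candidate gene is, "untestable" when
#' no tag SNP exists or no candidate expression is SNP-associated, and
#' "incompatible" otherwise. The verdict is invariant to flipping the
#' coded allele (all three signs flip coherently).
#'
#' @param G A [genotype_matrix()].
#' @param expr An [expression_matrix()].
#' @param covariates Covariate table (sample-aligned with G and expr).
#' @param lead_snp Lead SNP id.
#' @param phenotype Phenotype / risk factor name (see
#'   [default_schemes()]).
#' @param genes Candidate genes at the locus.
#' @param thresholds P-value thresholds for the three legs; defaults:
#'   SNP-phenotype 0.05, SNP-expression 3.9e-6, expression-phenotype
#'   0.05. Reported alongside the verdict so it can be re-derived.
#' @param schemes Adjustment schemes for the phenotype leg(s);
#'   expression legs are adjusted for age and sex.
#' @param lead_chrom,lead_pos,lead_codes Passed to [proxy_search()]
#'   when the lead SNP is off-panel.
#' @return Object of class `triangle_result` with per-gene legs and
#'   the locus verdict.
#' @export
triangle_test <- function(G, expr, covariates, lead_snp, phenotype,
                          genes,
                          thresholds = c(snp_pheno = 0.05,
                                         snp_expr = 3.9e-6,
                                         expr_pheno = 0.05),
                          schemes = default_schemes(),
                          lead_chrom = NULL, lead_pos = NULL,
                          lead_codes = NULL) {
  tag <- proxy_search(G, lead_snp, lead_chrom, lead_pos, lead_codes)
  base <- list(lead_snp = lead_snp, phenotype = phenotype,
               thresholds = thresholds)
  if (is.null(tag)) {
    return(structure(c(base, list(tag = NULL, genes = NULL,
                                  verdict = "untestable",
                                  reason = "no tag SNP with adequate r2")),
                     class = "triangle_result"))
  }
  g <- as.numeric(G$codes[, tag$snp])
  pheno <- rf_value(covariates, phenotype)
  covs <- schemes[[phenotype]]; if (is.null(covs)) covs <- c("age", "sex")
  Zp <- scheme_matrix(covariates, covs)
  Ze <- scheme_matrix(covariates, intersect(c("age", "sex"),
                                            c(names(covariates), "sex")))
  leg1 <- adjusted_assoc(pheno, g, Zp)

  rows <- lapply(genes, function(gene) {
    e <- expr$values[, gene]
    leg2 <- adjusted_assoc(e, g, Ze)
    leg3 <- adjusted_assoc(pheno, e, Zp)
    snp_assoc <- leg2$p < thresholds["snp_expr"]
    compatible <- leg1$p < thresholds["snp_pheno"] && snp_assoc &&
      leg3$p < thresholds["expr_pheno"] &&
      sign(leg2$beta) * sign(leg3$beta) == sign(leg1$beta)
    data.frame(gene = gene,
               p_snp_pheno = leg1$p, beta_snp_pheno = leg1$beta,
               p_snp_expr = leg2$p, beta_snp_expr = leg2$beta,
               p_expr_pheno = leg3$p, beta_expr_pheno = leg3$beta,
               snp_associated = snp_assoc, compatible = compatible,
               row.names = NULL)
  })
  gene_tab <- do.call(rbind, rows)
  verdict <- if (!any(gene_tab$snp_associated)) "untestable"
             else if (any(gene_tab$compatible)) "compatible"
             else "incompatible"
  structure(c(base, list(tag = tag, genes = gene_tab, verdict = verdict,
                         reason = NULL)),
            class = "triangle_result")
}

#' @export
print.triangle_result <- function(x, ...) {
  cat("triangle_test:", x$lead_snp, "->", x$phenotype, "\n")
  if (!is.null(x$tag))
    cat(sprintf("  tag SNP %s (r2 = %.2f)\n", x$tag$snp, x$tag$r2))
  cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$genes)) print(x$genes, digits = 3)
  invisible(x)
}

#' Outcome attenuation analysis
#'
#' Tests whether a risk factor's association with a count outcome (for
#' example carotid plaques) is attenuated once candidate mediator
#' expressions are adjusted for. Model A regresses the outcome on the
#' risk factor, age and sex; model B additionally includes the
#' mediator expressions. Both are ordinary linear regressions on the
#' counts (t-values reported); a Poisson log-linear fit is available as
#' an option. The verdict is "attenuated" when the risk factor is
#' significant (P < `alpha`) in model A but not in model B. Collinear
#' mediators are dropped with a warning.
#'
#' @param outcome Non-negative integer outcome vector.
#' @param rf_name Risk factor name (binary exposure such as
#'   "smoking").
#' @param mediators Gene names to adjust for (may be empty: model B
#'   then equals model A and the verdict is never "attenuated").
#' @param covariates Covariate table.
#' @param expr An [expression_matrix()].
#' @param alpha Significance level for the verdict (0.05).
#' @param family "linear" (default) or "poisson".
#' @return List with `model_a`, `model_b` (coefficient tables),
#'   `p_rf_a`, `p_rf_b`, `attenuated`, `dropped`.
#' @export
attenuation_test <- function(outcome, rf_name, mediators, covariates,
                             expr, alpha = 0.05, family = "linear") {
  stopifnot(all(outcome >= 0, na.rm = TRUE))
  x <- rf_value(covariates, rf_name)
  dat <- data.frame(outcome = outcome, rf = x,
                    age = covariates$age, sex = sex_code(covariates$sex))
  med <- intersect(mediators, colnames(expr$values))
  if (length(med) < length(mediators))
    stop("unknown mediator gene(s): ",
         paste(setdiff(mediators, med), collapse = ", "))
  M <- expr$values[, med, drop = FALSE]
  dropped <- character()
  fit_fun <- function(d) {
    if (family == "poisson") stats::glm(outcome ~ ., data = d,
                                        family = stats::poisson())
    else lm(outcome ~ ., data = d)
  }
  datB <- cbind(dat, as.data.frame(M))
  fa <- fit_fun(dat)
  fb <- fit_fun(datB)
  if (anyNA(coef(fb))) {
    aliased <- names(coef(fb))[is.na(coef(fb))]
    dropped <- med[make.names(med) %in% aliased]
    warning("dropping collinear mediator(s): ",
            paste(dropped, collapse = ", "))
    med <- setdiff(med, dropped)
    datB <- cbind(dat, as.data.frame(M[, med, drop = FALSE]))
    fb <- fit_fun(datB)
  }
  ca <- summary(fa)$coefficients
  cb <- summary(fb)$coefficients
  pcol <- ncol(ca)  # last column is the P-value for lm and glm alike
  p_rf_a <- ca["rf", pcol]
  p_rf_b <- cb["rf", pcol]
  attenuated <- length(med) > 0 && p_rf_a < alpha && p_rf_b >= alpha
  list(model_a = ca, model_b = cb, p_rf_a = p_rf_a, p_rf_b = p_rf_b,
       attenuated = attenuated, dropped = dropped, mediators = med)
}

#' Association of eSNPs with a clinical outcome
#'
#' Additive regression of the outcome on each SNP's dosage, adjusted
#' for age and sex, with Bonferroni correction for the number of SNPs
#' tested.
#'
#' @param G A [genotype_matrix()].
#' @param outcome Outcome vector (sample-aligned).
#' @param covariates Covariate table.
#' @param snps SNP ids to test (empty gives an empty table).
#' @return data.frame: snp, n, beta, t, p, p_bonf.
#' @export
esnp_outcome_test <- function(G, outcome, covariates, snps) {
  if (length(snps) == 0)
    return(data.frame(snp = character(), n = integer(), beta = numeric(),
                      t = numeric(), p = numeric(), p_bonf = numeric()))
  stopifnot(all(snps %in% colnames(G$codes)))
  Z <- cbind(1, age = covariates$age, sex = sex_code(covariates$sex))
  rows <- lapply(snps, function(s) {
    res <- adjusted_assoc(outcome, as.numeric(G$codes[, s]), Z)
    data.frame(snp = s, n = res$n, beta = res$beta, t = res$t, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(out$p * length(snps), 1)
  rownames(out) <- NULL
  out
}
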