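#' Simulate gene expression with planted effects
#'
#' Builds transformed-scale expression for every gene as
#' intercept + planted additive genotype terms + planted risk-factor
#' terms + optional genotype-by-risk-factor interaction terms +
#' Gaussian noise, then applies probe-polymorphism artifacts (a fixed
#' decrease per alternate allele of an in-probe SNP) to the measured
#' values. Betas requested through a target `r2` are scaled so the
#' term's expected share of total expression variance equals `r2`:
#' with known-variance terms totalling `v`, total variance is
#' `T = v / (1 - sum(r2))` and `beta = sqrt(r2 * T / var(x))`.
#'
#' @param genotypes A [genotype_matrix()] from [sim_genotypes()].
#' @param covariates Covariate table from [sim_risk_factors()].
#' @param config The same [sim_config()].
#' @return List with `expression` (an [expression_matrix()]) and
#'   `ledger` (a `ground_truth_ledger`: one row per planted effect with
#'   its resolved beta, target and realized variance fractions).
#' @export
sim_expression <- function(genotypes, covariates, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            is.data.frame(covariates),
            inherits(config, "sim_config"))
  layout <- sim_layout(config)
  ids <- sim_ids(config)
  n <- config$n_samples
  stopifnot(nrow(genotypes$codes) == n, nrow(covariates) == n)
  set.seed(derive_seed(config$seed, "expression"))

  rf_column <- function(rf) {
    if (rf %in% c("sex", "gender")) return(sex_code(covariates$sex))
    if (!rf %in% names(covariates)) stop("unknown risk factor: ", rf)
    covariates[[rf]]
  }
  geno_column <- function(snp) {
    g <- genotypes$codes[, snp]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  }

  # collect planted terms per gene
  terms <- list()
  add_term <- function(type, gene, x, beta, r2, snp = NA, rf = NA) {
    terms[[length(terms) + 1L]] <<- list(type = type, gene = gene, x = x,
                                         beta = beta, r2 = r2, snp = snp,
                                         rf = rf)
  }
  for (type in c("cis", "trans")) {
    df <- config[[paste0(type, "_effects")]]
    if (is.null(df)) next
    for (k in seq_len(nrow(df)))
      add_term(type, df$gene[k], geno_column(df$snp[k]),
               df$beta[k], df$r2[k], snp = df$snp[k])
  }
  if (!is.null(config$rf_effects)) {
    df <- config$rf_effects
    for (k in seq_len(nrow(df)))
      add_term("rf", df$gene[k], rf_column(df$rf[k]),
               df$beta[k], df$r2[k], rf = df$rf[k])
  }
  if (!is.null(config$interaction_effects)) {
    df <- config$interaction_effects
    for (k in seq_len(nrow(df))) {
      g <- geno_column(df$snp[k]); r <- rf_column(df$rf[k])
      add_term("interaction", df$gene[k],
               (g - mean(g)) * (r - mean(r)),
               df$beta[k], NA_real_, snp = df$snp[k], rf = df$rf[k])
    }
  }

  values <- matrix(0, n, config$n_genes,
                   dimnames = list(ids$samples, ids$genes))
  ledger_rows <- list()
  gene_of <- vapply(terms, function(t) t$gene, character(1))
  for (j in seq_len(config$n_genes)) {
    gene <- ids$genes[j]
    tj <- terms[gene_of == gene]
    var_known <- config$noise_sd^2
    sum_r2 <- 0
    for (t in tj) {
      if (!is.na(t$beta)) var_known <- var_known + t$beta^2 * var(t$x)
      else sum_r2 <- sum_r2 + t$r2
    }
    if (sum_r2 >= 1)
      stop("requested variance fractions for gene ", gene, " total >= 1")
    total_var <- var_known / (1 - sum_r2)
    y <- rep(7, n)  # arbitrary intercept on the arcsinh-intensity scale
    for (t in tj) {
      beta <- if (!is.na(t$beta)) t$beta else sqrt(t$r2 * total_var / var(t$x))
      y <- y + beta * t$x
      ledger_rows[[length(ledger_rows) + 1L]] <-
        data.frame(type = t$type, gene = gene, snp = t$snp, rf = t$rf,
                   beta = beta, r2_target = t$r2, r2_realized = NA_real_,
                   stringsAsFactors = FALSE)
    }
    values[, j] <- y + rnorm(n, 0, config$noise_sd)
  }

  # probe artifacts perturb the measured values only
  if (!is.null(config$probe_artifacts)) {
    df <- config$probe_artifacts
    for (k in seq_len(nrow(df))) {
      g <- geno_column(df$snp[k])
      values[, df$gene[k]] <- values[, df$gene[k]] - df$attenuation[k] * g
      ledger_rows[[length(ledger_rows) + 1L]] <-
        data.frame(type = "artifact", gene = df$gene[k], snp = df$snp[k],
                   rf = NA, beta = -df$attenuation[k],
                   r2_target = NA_real_, r2_realized = NA_real_,
                   stringsAsFactors = FALSE)
    }
  }

  effects <- if (length(ledger_rows)) do.call(rbind, ledger_rows)
             else data.frame(type = character(), gene = character(),
                             snp = character(), rf = character(),
                             beta = numeric(), r2_target = numeric(),
                             r2_realized = numeric())
  # realized univariate variance fractions, for parameter-recovery tests
  for (i in seq_len(nrow(effects))) {
    x <- switch(effects$type[i],
                cis = , trans = , artifact = geno_column(effects$snp[i]),
                rf = rf_column(effects$rf[i]),
                interaction = NULL)
    if (!is.null(x))
      effects$r2_realized[i] <- cor(x, values[, effects$gene[i]])^2
  }

  ledger <- structure(list(effects = effects, seed = config$seed),
                      class = "ground_truth_ledger")
  list(expression = expression_matrix(values, layout$gene_meta),
       ledger = ledger)
}

#' @export
print.ground_truth_ledger <- function(x, ...) {
  cat("ground_truth_ledger:", nrow(x$effects), "planted effects\n")
  if (nrow(x$effects)) print(table(x$effects$type))
  invisible(x)
}
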