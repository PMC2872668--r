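#' Simulate per-gene detection P-values
#'
#' Emulates negative-control-based detection calls: genes selected as
#' undetected (Bernoulli at `frac_undetected`) receive detection
#' P-values uniform on (0.05, 1) in every sample; detected genes
#' receive P-values uniform on (0, 0.01). Designed so
#' [detection_filter()] at its defaults keeps exactly the detected
#' genes.
#'
#' @param expr An [expression_matrix()] (defines samples and genes).
#' @param frac_undetected Fraction of genes simulated as undetected.
#' @param seed Seed for this stream.
#' @return List with `detection` (samples-by-genes P-value matrix) and
#'   `undetected` (character vector of the genes drawn as undetected).
#' @export
sim_detection_pvalues <- function(expr, frac_undetected = 0, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"),
            frac_undetected >= 0, frac_undetected <= 1)
  values <- expr$values
  n <- nrow(values); g <- ncol(values)
  set.seed(derive_seed(seed, "detection"))
  undetected <- runif(g) < frac_undetected
  det <- matrix(runif(n * g, 0, 0.01), n, g, dimnames = dimnames(values))
  if (any(undetected))
    det[, undetected] <- runif(n * sum(undetected), 0.05, 1)
  list(detection = det, undetected = colnames(values)[undetected])
}

#' Simulate carotid plaque counts
#'
#' Plaque counts are Poisson with log mean linear in smoking status and
#' in the (standardized) expression of named mediator genes:
#' `count ~ Poisson(exp(intercept + b_smoking * smoking + sum b_g * z(expr_g)))`.
#' A fully mediated design sets `smoking = 0` in the link and routes
#' the whole smoking effect through the mediator genes.
#'
#' @param covariates Covariate table (needs a binary `smoking` column).
#' @param expr An [expression_matrix()].
#' @param link List with `intercept` (default `log(0.5)`), `smoking`
#'   (direct smoking coefficient, default 0) and `genes` (named vector
#'   of coefficients on standardized gene expression, default none).
#' @param seed Seed for this stream.
#' @return Integer vector of plaque counts, one per sample.
#' @export
sim_plaques <- function(covariates, expr, link = list(), seed = 1L) {
  stopifnot(is.data.frame(covariates), inherits(expr, "expression_matrix"))
  intercept <- if (is.null(link$intercept)) log(0.5) else link$intercept
  b_smoke <- if (is.null(link$smoking)) 0 else link$smoking
  genes <- link$genes
  eta <- rep(intercept, nrow(covariates))
  if (b_smoke != 0) {
    stopifnot(!is.null(covariates$smoking))
    eta <- eta + b_smoke * covariates$smoking
  }
  if (!is.null(genes) && length(genes)) {
    if (!all(names(genes) %in% colnames(expr$values)))
      stop("link names a gene absent from the expression matrix")
    for (g in names(genes)) {
      x <- expr$values[, g]
      eta <- eta + genes[[g]] * (x - mean(x)) / sd(x)
    }
  }
  set.seed(derive_seed(seed, "plaques"))
  rpois(length(eta), exp(eta))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [sim_genotypes()], [sim_risk_factors()],
#' [sim_expression()], [sim_detection_pvalues()] and optionally
#' [sim_plaques()] under one master seed.
#'
#' @param config A [sim_config()].
#' @param frac_undetected Fraction of genes simulated as undetected.
#' @param plaque_link Optional link list for [sim_plaques()]; `NULL`
#'   skips the outcome (plaque counts set to 0).
#' @return List with `genotypes`, `covariates` (including
#'   `plaque_count`), `expression`, `detection`, `ledger`.
#' @export
sim_cohort <- function(config, frac_undetected = 0, plaque_link = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- sim_genotypes(config)
  covariates <- sim_risk_factors(config)
  ex <- sim_expression(genotypes, covariates, config)
  det <- sim_detection_pvalues(ex$expression, frac_undetected,
                               seed = config$seed)
  covariates$plaque_count <- if (is.null(plaque_link)) {
    rep(0L, config$n_samples)
  } else {
    sim_plaques(covariates, ex$expression, plaque_link, seed = config$seed)
  }
  ledger <- ex$ledger
  ledger$plaque_link <- plaque_link
  list(genotypes = genotypes, covariates = covariates,
       expression = ex$expression, detection = det$detection,
       undetected = det$undetected, ledger = ledger)
}
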