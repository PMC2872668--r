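#' Pipeline configuration
#'
#' Bundles every input path or simulation config, every analysis
#' threshold (all defaulting to the study-wise values used throughout
#' the package), and the master seed for one end-to-end run.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()] to simulate the cohort, or NULL to read
#'   inputs from files.
#' @param inputs When `sim` is NULL: named list of paths
#'   (`dosage_tsv` or `vcf`, `expression_tsv`, `detection_tsv`,
#'   `gene_bed`, `covariates_tsv`).
#' @param apply_arcsinh Apply the arcsinh transform to the expression
#'   input (TRUE for raw intensities; the simulator already emits the
#'   transformed scale, so the default is FALSE when `sim` is given).
#' @param frac_undetected Fraction of undetected genes when
#'   simulating.
#' @param plaque_link Optional outcome link for [sim_plaques()].
#' @param store_below,study_wise,kw_threshold,min_homozygotes
#'   [genome_scan()] parameters.
#' @param cis_window cis window in bp (1e6).
#' @param rf_threshold Risk-factor scan threshold (3.9e-7).
#' @param stability_rfs Risk factors to run stability selection on.
#' @param n_reps,freq_min,screen_p,p_enter [stability_select()]
#'   parameters.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, inputs = NULL,
                            apply_arcsinh = is.null(sim),
                            frac_undetected = 0, plaque_link = NULL,
                            store_below = 1e-5, study_wise = 5.78e-12,
                            kw_threshold = 1e-10, min_homozygotes = 30,
                            cis_window = 1e6, rf_threshold = 3.9e-7,
                            stability_rfs = "smoking", n_reps = 25,
                            freq_min = 0.25, screen_p = 3.9e-6,
                            p_enter = 0.01, seed = 1L) {
  if (is.null(sim) && is.null(inputs))
    stop("either a sim_config or input paths are required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> expression/genotype QC -> genome
#' scan -> cis/trans annotation and tiered summary -> risk-factor scan
#' and cis-eSNP enrichment -> interaction scan -> stability selection
#' -> attenuation analysis (when an outcome is present) -> design
#' report. Every stage writes a TSV artifact into `out_dir` and a YAML
#' manifest records inputs, parameters, seed, package version and
#' per-stage status; on a stage failure the manifest marks the failed
#' stage and the error is re-thrown.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("monoqtl")),
    seed = config$seed,
    parameters = config[c("store_below", "study_wise", "kw_threshold",
                          "min_homozygotes", "cis_window", "rf_threshold",
                          "n_reps", "freq_min", "screen_p", "p_enter",
                          "apply_arcsinh")],
    inputs = if (is.null(config$sim)) config$inputs else "simulated",
    stages = list())
  art <- function(name) file.path(config$out_dir, name)
  write_manifest <- function()
    yaml::write_yaml(manifest, art("manifest.yaml"))
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  data <- stage("input", function() {
    if (!is.null(config$sim)) {
      co <- sim_cohort(config$sim, config$frac_undetected,
                       config$plaque_link)
      write_ledger_yaml(co$ledger, art("ledger.yaml"))
      co
    } else {
      inp <- config$inputs
      geno <- if (!is.null(inp$vcf)) read_vcf(inp$vcf)
              else read_dosage_tsv(inp$dosage_tsv)
      values <- read_expression_tsv(inp$expression_tsv)
      gene_meta <- read_bed(inp$gene_bed)
      detection <- if (!is.null(inp$detection_tsv))
        read_expression_tsv(inp$detection_tsv) else NULL
      list(genotypes = geno,
           expression = expression_matrix(values, gene_meta),
           detection = detection,
           covariates = read_covariates_tsv(inp$covariates_tsv),
           ledger = NULL)
    }
  })

  qc <- stage("qc", function() {
    expr <- data$expression
    if (config$apply_arcsinh) expr <- arcsinh_transform(expr)
    expr <- quantile_normalize(expr)
    keep <- colnames(expr$values)
    if (!is.null(data$detection))
      keep <- intersect(keep, detection_filter(data$detection))
    keep <- filter_gene_symbols(keep)
    expr$values <- expr$values[, keep, drop = FALSE]
    expr$gene_meta <- expr$gene_meta[match(keep, expr$gene_meta$gene), ,
                                     drop = FALSE]
    gq <- genotype_qc(data$genotypes)
    covs <- prepare_covariates(data$covariates)
    write.table(gq$report, art("genotype_qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_expression_tsv(expr, art("expression_qc.tsv"))
    list(expression = expr, genotypes = gq$genotypes, covariates = covs)
  })

  scan <- stage("scan", function() {
    sc <- genome_scan(qc$expression, qc$genotypes, qc$covariates,
                      store_below = config$store_below,
                      study_wise = config$study_wise,
                      kw_threshold = config$kw_threshold,
                      min_homozygotes = config$min_homozygotes)
    sc <- annotate_cis_trans(sc, config$cis_window)
    write.table(as.data.frame(sc), art("scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sc
  })

  summary_tab <- stage("annotate", function() {
    tab <- summarize_eqtls(scan,
                           tiers = c(config$store_below, 1e-8,
                                     config$study_wise))
    write.table(as.data.frame(tab), art("eqtl_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  rf <- stage("rf_assoc", function() {
    res <- rf_assoc_scan(qc$expression, qc$covariates,
                         threshold = config$rf_threshold)
    write.table(res, art("rf_assoc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })

  enrich <- stage("enrichment", function() {
    sig <- scan[scan$study_wise & scan$cis_trans == "cis", , drop = FALSE]
    cis_genes <- unique(sig$gene)
    all_genes <- colnames(qc$expression$values)
    rows <- lapply(unique(rf$rf), function(r) {
      rf_genes <- unique(rf$gene[rf$rf == r & rf$significant])
      a <- length(intersect(rf_genes, cis_genes))
      b <- length(setdiff(rf_genes, cis_genes))
      other <- setdiff(all_genes, rf_genes)
      cc <- length(intersect(other, cis_genes))
      d <- length(setdiff(other, cis_genes))
      er <- enrichment_or(a, b, cc, d)
      data.frame(rf = r, n_rf = a + b, n_rf_cis = a, or = er$or,
                 ci_low = er$ci[1], ci_high = er$ci[2])
    })
    out <- do.call(rbind, rows)
    write.table(out, art("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out
  })

  interact <- stage("interaction", function() {
    sig <- scan[scan$study_wise & scan$cis_trans == "cis", , drop = FALSE]
    rf_sig <- rf[rf$significant, , drop = FALSE]
    pairs <- NULL
    if (nrow(sig) && nrow(rf_sig)) {
      best <- do.call(rbind, lapply(split(sig, sig$gene), function(d)
        d[which.min(d$p_anova), c("gene", "snp")]))
      pairs <- merge(best, rf_sig[, c("gene", "rf")], by = "gene")
    }
    if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
    out <- interaction_scan(qc$expression, qc$genotypes, qc$covariates,
                            pairs, min_homozygotes = config$min_homozygotes)
    write.table(out, art("interaction.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out
  })

  stab <- stage("stability", function() {
    res <- lapply(config$stability_rfs, function(r)
      stability_select(qc$expression, qc$covariates, r,
                       n_reps = config$n_reps,
                       freq_min = config$freq_min,
                       screen_p = config$screen_p,
                       p_enter = config$p_enter,
                       master_seed = config$seed))
    names(res) <- config$stability_rfs
    tab <- do.call(rbind, lapply(res, function(x)
      if (nrow(x$reported)) cbind(rf = x$rf, x$reported) else NULL))
    if (!is.null(tab))
      write.table(tab, art("stability.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    res
  })

  mediate <- stage("mediation", function() {
    if (is.null(qc$covariates$plaque_count) ||
        all(qc$covariates$plaque_count == 0)) return(NULL)
    smoking_genes <- if (!is.null(stab$smoking))
      stab$smoking$reported$gene else character()
    if (length(smoking_genes) == 0) return(NULL)
    res <- attenuation_test(qc$covariates$plaque_count, "smoking",
                            smoking_genes, qc$covariates, qc$expression)
    out <- data.frame(term = rownames(res$model_b),
                      t = res$model_b[, 3], p = res$model_b[, 4])
    write.table(out, art("attenuation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })

  design <- stage("design", function() {
    n <- nrow(qc$expression$values)
    out <- data.frame(
      quantity = c("study_wise_threshold", "min_detectable_r2",
                   "power_r2_0.04"),
      value = c(config$study_wise,
                min_detectable_r2(config$study_wise, n),
                power_single_snp(n, config$study_wise, 0.04)))
    write.table(out, art("design.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out
  })

  write_manifest()
  invisible(list(data = data, qc = qc, scan = scan,
                 summary = summary_tab, rf = rf, enrichment = enrich,
                 interaction = interact, stability = stab,
                 mediation = mediate, design = design,
                 out_dir = config$out_dir))
}
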