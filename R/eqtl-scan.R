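#' Genome-wide SNP-by-expression association scan
#'
#' Tests every SNP against every expression trait by one-way ANOVA on
#' genotype groups (see [group_genotypes()]): three groups, or two when
#' minor homozygotes are rare. Records with ANOVA P below `store_below`
#' are retained; for those, the Kruskal-Wallis confirmation P-value and
#' an additive-coding slope (effect direction) are computed.
#' An association is flagged study-wise significant when the ANOVA P is
#' below `study_wise` AND the Kruskal-Wallis P is below `kw_threshold`.
#' SNPs on chromosome X are tested separately per sex and combined with
#' Fisher's method (see [chrx_assoc()]); this requires `covariates`
#' with a `sex` column.
#'
#' The heavy lifting is a closed-form vectorized ANOVA over all SNPs at
#' once (group sums by matrix product), algebraically identical to
#' per-pair `lm()` fits.
#'
#' @param expr An [expression_matrix()] (transformed scale, no missing
#'   values).
#' @param geno A [genotype_matrix()], sample-aligned with `expr`.
#' @param covariates Optional covariate table (`sex` used for X SNPs).
#' @param store_below Persist records with ANOVA P below this (1e-5).
#' @param study_wise Study-wise ANOVA significance threshold
#'   (default 5.78e-12, the Bonferroni level for ~675k SNPs x ~12.8k
#'   expressions).
#' @param kw_threshold Kruskal-Wallis confirmation threshold (1e-10).
#' @param min_homozygotes Genotype-group merging threshold (30).
#'
#' @return data.frame of stored associations (class `eqtl_scan`),
#'   sorted by (gene, P), with columns snp, chrom, pos, gene,
#'   gene_chrom, gene_start, gene_end, n, groups, F, R2, p_anova, p_kw,
#'   beta_additive, study_wise, combined_x. Attributes: `n_tests`,
#'   `n_untestable`, `thresholds`.
#' @export
genome_scan <- function(expr, geno, covariates = NULL,
                        store_below = 1e-5, study_wise = 5.78e-12,
                        kw_threshold = 1e-10, min_homozygotes = 30) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(geno, "genotype_matrix"))
  if (ncol(geno$codes) == 0)
    return(empty_scan(store_below, study_wise, kw_threshold))
  if (!identical(rownames(expr$values), rownames(geno$codes)))
    stop("sample ids of expression and genotype matrices do not match")
  if (anyNA(expr$values)) stop("expression matrix contains missing values")

  is_x <- geno$snp_meta$chrom %in% c("X", "chrX", "23")
  auto <- which(!is_x); xsnp <- which(is_x)
  if (length(xsnp) > 0 && (is.null(covariates) || is.null(covariates$sex)))
    stop("X-chromosome SNPs present: covariates with a sex column required")

  values <- expr$values
  gm <- expr$gene_meta
  records <- list()
  n_tests <- 0L; n_untestable <- 0L

  scan_block <- function(codes_block, snp_idx) {
    eng <- scan_engine(codes_block, min_homozygotes)
    n_untestable <<- n_untestable + sum(!eng$testable)
    ok <- which(eng$testable)
    if (length(ok) == 0) return(NULL)
    for (j in seq_len(ncol(values))) {
      res <- eng$test(values[, j])
      n_tests <<- n_tests + length(ok)
      hit <- ok[which(res$p[ok] < store_below)]
      if (length(hit) == 0) next
      for (s in hit) {
        lab <- eng$labels[, s]
        kw <- kw_confirm(values[, j], lab)
        records[[length(records) + 1L]] <<- data.frame(
          snp = colnames(codes_block)[s],
          gene = colnames(values)[j],
          n = eng$ncall[s], groups = eng$ngroups[s],
          F = res$f[s], R2 = res$r2[s], p_anova = res$p[s], p_kw = kw,
          beta_additive = additive_beta(values[, j], codes_block[, s]),
          combined_x = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  if (length(auto) > 0)
    scan_block(geno$codes[, auto, drop = FALSE], auto)

  if (length(xsnp) > 0) {
    sexc <- sex_code(covariates$sex)
    for (s in xsnp) {
      codes <- geno$codes[, s]
      for (j in seq_len(ncol(values))) {
        res <- tryCatch(
          chrx_assoc(values[, j], codes, sexc, min_homozygotes),
          error = function(e) NULL)
        if (is.null(res)) { n_untestable <- n_untestable + 1L; next }
        n_tests <- n_tests + 1L
        if (res$p >= store_below) next
        ok2 <- !is.na(codes)
        records[[length(records) + 1L]] <- data.frame(
          snp = geno$snp_meta$snp[s], gene = colnames(values)[j],
          n = sum(ok2), groups = NA_integer_,
          F = NA_real_, R2 = res$r2, p_anova = res$p, p_kw = res$kw_p,
          beta_additive = additive_beta(values[, j], codes),
          combined_x = TRUE, stringsAsFactors = FALSE)
      }
    }
  }

  out <- if (length(records)) do.call(rbind, records)
         else empty_scan(store_below, study_wise, kw_threshold)[0, ]
  if (nrow(out)) {
    si <- match(out$snp, geno$snp_meta$snp)
    gi <- match(out$gene, gm$gene)
    out$chrom <- geno$snp_meta$chrom[si]
    out$pos <- geno$snp_meta$pos[si]
    out$gene_chrom <- gm$chrom[gi]
    out$gene_start <- gm$start[gi]
    out$gene_end <- gm$end[gi]
    out$study_wise <- out$p_anova < study_wise & out$p_kw < kw_threshold
    out <- out[order(out$gene, out$p_anova), ]
    rownames(out) <- NULL
    out <- out[, c("snp", "chrom", "pos", "gene", "gene_chrom",
                   "gene_start", "gene_end", "n", "groups", "F", "R2",
                   "p_anova", "p_kw", "beta_additive", "study_wise",
                   "combined_x")]
  }
  structure(out, class = c("eqtl_scan", "data.frame"),
            n_tests = n_tests, n_untestable = n_untestable,
            thresholds = c(store_below = store_below,
                           study_wise = study_wise,
                           kw = kw_threshold))
}

empty_scan <- function(store_below, study_wise, kw_threshold) {
  structure(
    data.frame(snp = character(), chrom = character(), pos = numeric(),
               gene = character(), gene_chrom = character(),
               gene_start = numeric(), gene_end = numeric(),
               n = integer(), groups = integer(), F = numeric(),
               R2 = numeric(), p_anova = numeric(), p_kw = numeric(),
               beta_additive = numeric(), study_wise = logical(),
               combined_x = logical()),
    class = c("eqtl_scan", "data.frame"), n_tests = 0L,
    n_untestable = 0L,
    thresholds = c(store_below = store_below, study_wise = study_wise,
                   kw = kw_threshold))
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eqtl_scan:", attr(x, "n_tests"), "tests,", nrow(x),
      "stored associations,", sum(x$study_wise), "study-wise significant\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# Vectorized one-way ANOVA engine over a block of SNPs.
# Precomputes merged genotype-group indicator matrices once, then tests
# any expression vector against all SNPs with a handful of crossprods.
scan_engine <- function(codes, min_homozygotes = 30) {
  n <- nrow(codes); S <- ncol(codes)
  labels <- matrix(NA_integer_, n, S)
  ngroups <- integer(S); testable <- logical(S)
  for (s in seq_len(S)) {
    g <- group_genotypes(codes[, s], min_homozygotes)
    labels[, s] <- g$labels
    ngroups[s] <- g$n_groups
    testable[s] <- g$testable
  }
  I1 <- (labels == 1L); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (labels == 2L); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  I3 <- (labels == 3L); I3[is.na(I3)] <- FALSE; storage.mode(I3) <- "double"
  M <- I1 + I2 + I3
  n1 <- colSums(I1); n2 <- colSums(I2); n3 <- colSums(I3)
  ncall <- n1 + n2 + n3
  df1 <- ngroups - 1L
  df2 <- ncall - ngroups

  test <- function(e) {
    t1 <- as.vector(crossprod(M, e))
    q <- as.vector(crossprod(M, e^2))
    s1 <- as.vector(crossprod(I1, e))
    s2 <- as.vector(crossprod(I2, e))
    s3 <- as.vector(crossprod(I3, e))
    grand <- t1^2 / pmax(ncall, 1)
    ssb <- ifelse(n1 > 0, s1^2 / pmax(n1, 1), 0) +
      ifelse(n2 > 0, s2^2 / pmax(n2, 1), 0) +
      ifelse(n3 > 0, s3^2 / pmax(n3, 1), 0) - grand
    sst <- q - grand
    ssw <- pmax(sst - ssb, 0)
    f <- (ssb / pmax(df1, 1)) / (ssw / pmax(df2, 1))
    p <- pf(f, df1, df2, lower.tail = FALSE)
    r2 <- ssb / sst
    degenerate <- !testable | sst <= .Machine$double.eps * pmax(q, 1)
    p[degenerate] <- 1; r2[degenerate] <- 0; f[degenerate] <- 0
    list(f = f, p = p, r2 = r2)
  }
  list(test = test, labels = labels, ngroups = ngroups,
       testable = testable, ncall = ncall)
}
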