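#' Expression matrix container
#'
#' Samples-by-genes expression values together with per-gene annotation.
#' Values are raw intensities before [arcsinh_transform()] and transformed
#' intensities afterwards; all downstream association code assumes the
#' transformed scale.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (colnames = gene symbols).
#' @param gene_meta data.frame with one row per gene: `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive interval of the gene) and
#'   optionally `probe_start`, `probe_end` (interval of the array probe).
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_meta) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !is.null(rownames(values)),
            is.data.frame(gene_meta),
            all(c("gene", "chrom", "start", "end") %in% names(gene_meta)))
  gene_meta <- gene_meta[match(colnames(values), gene_meta$gene), , drop = FALSE]
  if (anyNA(gene_meta$gene)) stop("gene_meta is missing annotation for some genes")
  if (any(gene_meta$start > gene_meta$end)) stop("gene intervals must satisfy start <= end")
  if (anyDuplicated(colnames(values))) stop("duplicate gene symbols")
  rownames(gene_meta) <- NULL
  structure(list(values = values, gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "genes\n")
  cat("  chromosomes:", paste(sort(unique(x$gene_meta$chrom)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Genotype matrix container
#'
#' Samples-by-SNPs additive minor-allele dosages in {0, 1, 2, NA}
#' together with SNP metadata.
#'
#' @param codes Integer/numeric matrix, samples in rows (rownames =
#'   sample ids), SNPs in columns (colnames = SNP ids); values 0, 1, 2
#'   or NA (missing call).
#' @param snp_meta data.frame with one row per SNP: `snp`, `chrom`,
#'   `pos` (1-based bp), and optionally `maf`, `call_rate`, `hwe_p`
#'   filled in by [genotype_qc()].
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snp_meta) {
  stopifnot(is.matrix(codes),
            ncol(codes) == 0 || !is.null(colnames(codes)),
            !is.null(rownames(codes)),
            is.data.frame(snp_meta),
            all(c("snp", "chrom", "pos") %in% names(snp_meta)))
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  snp_meta <- snp_meta[match(colnames(codes), snp_meta$snp), , drop = FALSE]
  if (anyNA(snp_meta$snp)) stop("snp_meta is missing some SNPs")
  rownames(snp_meta) <- NULL
  structure(list(codes = codes, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "samples x", ncol(x$codes), "SNPs\n")
  cat("  chromosomes:", paste(sort(unique(x$snp_meta$chrom)), collapse = ", "), "\n")
  miss <- mean(is.na(x$codes))
  if (miss > 0) cat(sprintf("  missing call rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

# Subset a genotype_matrix by sample index and/or SNP id/index.
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  codes <- G$codes
  if (!is.null(samples)) codes <- codes[samples, , drop = FALSE]
  if (!is.null(snps)) codes <- codes[, snps, drop = FALSE]
  genotype_matrix(codes, G$snp_meta[match(colnames(codes), G$snp_meta$snp), ,
                                    drop = FALSE])
}
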