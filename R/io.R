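# Plain-text interchange: TSV for matrices and tables, BED for
# intervals (0-based half-open on disk, 1-based inclusive in memory),
# VCF for genotypes, YAML for the simulation ledger.

#' Write / read a genes-by-samples TSV matrix
#'
#' On disk the matrix is genes in rows with a `gene` column and one
#' column per sample; in memory the package uses samples-by-genes
#' orientation. Used for expression and detection P-value matrices.
#'
#' @param x Samples-by-genes matrix or [expression_matrix()].
#' @param path Output file.
#' @export
write_expression_tsv <- function(x, path) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  df <- data.frame(gene = colnames(values), t(values),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv` returns a samples-by-genes matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$gene
  m
}

#' Write / read additive genotype dosages as TSV
#'
#' SNPs in rows with `snp`, `chrom`, `pos` columns followed by one
#' dosage column per sample (0/1/2, NA for missing calls).
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- data.frame(snp = G$snp_meta$snp, chrom = G$snp_meta$chrom,
                   pos = G$snp_meta$pos, t(G$codes), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_dosage_tsv
#' @return `read_dosage_tsv` returns a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = c(chrom = "character"))
  codes <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(codes) <- df$snp
  genotype_matrix(codes, df[, 1:3])
}

#' Write / read intervals as BED
#'
#' BED is 0-based half-open; in-memory intervals are 1-based
#' inclusive, so writing subtracts 1 from the start and reading adds
#' it back.
#'
#' @param meta data.frame with `gene`, `chrom` and either
#'   `start`/`end` or `probe_start`/`probe_end`.
#' @param path Output file.
#' @param what "gene" (default) or "probe": which interval columns to
#'   write.
#' @export
write_bed <- function(meta, path, what = c("gene", "probe")) {
  what <- match.arg(what)
  s <- if (what == "gene") meta$start else meta$probe_start
  e <- if (what == "gene") meta$end else meta$probe_end
  df <- data.frame(chrom = meta$chrom, start = s - 1, end = e,
                   name = meta$gene)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname write_bed
#' @return `read_bed` returns a data.frame with `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  data.frame(gene = df[[4]], chrom = df[[1]], start = df[[2]] + 1,
             end = df[[3]])
}

#' Write / read the covariate table as TSV
#'
#' @param covariates Covariate data.frame.
#' @param path Output file.
#' @export
write_covariates_tsv <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write genotypes as an uncompressed VCF
#'
#' Minimal VCF 4.2 with one contig line per chromosome and GT fields
#' (dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, missing -> ./.). Alleles are
#' placeholders (REF A, ALT G): the simulator models dosages, not
#' nucleotides.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=monoqtl", con)
  for (ch in unique(G$snp_meta$chrom))
    writeLines(sprintf("##contig=<ID=%s>", ch), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  samples <- rownames(G$codes)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G$codes))) {
    g <- G$codes[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    writeLines(paste(c(G$snp_meta$chrom[j],
                       format(G$snp_meta$pos[j], scientific = FALSE),
                       G$snp_meta$snp[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields with \pkg{vcfR} and returns alternate-allele
#' dosages.
#'
#' @param path VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  codes <- t(vapply(colnames(gt), function(s) count_alt(gt[, s]),
                    integer(nrow(gt))))
  colnames(codes) <- rownames(gt)
  fix <- vcfR::getFIX(v)
  meta <- data.frame(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]))
  genotype_matrix(codes, meta)
}

#' Write / read the ground-truth ledger as YAML
#'
#' @param ledger A `ground_truth_ledger` from [sim_expression()].
#' @param path Output file.
#' @export
write_ledger_yaml <- function(ledger, path) {
  stopifnot(inherits(ledger, "ground_truth_ledger"))
  yaml::write_yaml(list(seed = ledger$seed,
                        effects = lapply(seq_len(nrow(ledger$effects)),
                                         function(i)
                                           as.list(ledger$effects[i, ])),
                        plaque_link = ledger$plaque_link),
                   path, precision = 15)
}

#' @rdname write_ledger_yaml
#' @export
read_ledger_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  effects <- do.call(rbind, lapply(raw$effects, function(e)
    as.data.frame(lapply(e, function(v) if (is.null(v)) NA else v))))
  structure(list(effects = effects, seed = raw$seed,
                 plaque_link = raw$plaque_link),
            class = "ground_truth_ledger")
}
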