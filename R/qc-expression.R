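#' Variance-stabilizing arcsinh transform
#'
#' Elementwise `x -> ln(x + sqrt(x^2 + 1))`. Unlike the log transform it
#' is defined for the negative intensities that background-corrected
#' bead-array data can produce, and it is strictly increasing, so
#' within-sample ranks are preserved.
#'
#' @param x Numeric vector/matrix or an [expression_matrix()].
#' @return Same shape as the input, transformed.
#' @export
arcsinh_transform <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$values <- asinh(x$values)
    return(x)
  }
  asinh(x)
}

#' Quantile normalization across samples
#'
#' Forces every sample's expression distribution onto the common
#' reference distribution (the across-sample mean of order statistics),
#' preserving within-sample ranks. Tied values receive the mean of their
#' tied reference values. Delegates to [limma::normalizeQuantiles()],
#' the standard array implementation of this transform.
#'
#' @param x Samples-by-genes numeric matrix or [expression_matrix()].
#' @return Same shape, quantile-normalized across samples.
#' @export
quantile_normalize <- function(x) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(is.matrix(values), nrow(values) >= 2)
  if (any(colSums(!is.na(t(values))) == 0))
    stop("sample with all values missing")
  # limma works on probes x arrays, our orientation is samples x genes
  norm <- t(limma::normalizeQuantiles(t(values), ties = TRUE))
  dimnames(norm) <- dimnames(values)
  if (inherits(x, "expression_matrix")) {
    x$values <- norm
    return(x)
  }
  norm
}

#' Detection filter on background-corrected expression
#'
#' A gene is considered expressed above background when its detection
#' P-value is below `p_cut` in strictly more than `sample_frac` of the
#' samples.
#'
#' @param detect Samples-by-genes matrix of detection P-values.
#' @param p_cut Detection P-value cutoff (default 0.05).
#' @param sample_frac Required fraction of samples (default 0.05,
#'   strict inequality).
#' @return Character vector of kept gene names.
#' @export
detection_filter <- function(detect, p_cut = 0.05, sample_frac = 0.05) {
  stopifnot(is.matrix(detect), !is.null(colnames(detect)))
  n_detected <- colSums(detect < p_cut, na.rm = TRUE)
  colnames(detect)[n_detected > sample_frac * nrow(detect)]
}

#' Drop poorly characterized gene symbols
#'
#' Removes putative / non-well-characterized transcripts by symbol:
#' names starting with KIAA, FLJ, HS, MGC or LOC, and open-reading-frame
#' placeholders matching `C<number>orf`. Matching is case-sensitive.
#'
#' @param symbols Character vector of gene symbols.
#' @return The kept subset, in input order.
#' @export
filter_gene_symbols <- function(symbols) {
  drop <- grepl("^(KIAA|FLJ|HS|MGC|LOC)", symbols) |
    grepl("^C[0-9]+orf", symbols)
  symbols[!drop]
}
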