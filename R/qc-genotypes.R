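#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square comparing observed genotype counts with the counts
#' expected under Hardy-Weinberg proportions at the observed allele
#' frequency, without continuity correction. Monomorphic SNPs carry no
#' testable deviation and return P = 1.
#'
#' @param counts Integer vector of length 3: genotype counts for minor
#'   allele dosage 0, 1, 2 (non-missing samples only).
#' @return List with `chisq` and `p`.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_))
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) return(list(chisq = 0, p = 1))
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Keeps a SNP iff minor allele frequency > `maf_min`, genotype call
#' rate > `call_rate_min` and the Hardy-Weinberg equilibrium P-value
#' (see [hwe_test()]) > `hwe_p_min`; all inequalities strict. SNPs with
#' zero non-missing calls are dropped with reason "no data".
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minor allele frequency threshold (default 0.01).
#' @param call_rate_min Call-rate threshold (default 0.98).
#' @param hwe_p_min HWE P-value threshold (default 1e-4).
#'
#' @return List with `genotypes` (the kept [genotype_matrix()], with
#'   `maf`, `call_rate`, `hwe_p` filled into `snp_meta`) and `report`, a
#'   per-SNP data.frame of the computed statistics, keep decision and
#'   failure reasons, plus per-criterion exclusion counts in
#'   `attr(report, "exclusions")`.
#' @export
genotype_qc <- function(G, maf_min = 0.01, call_rate_min = 0.98,
                        hwe_p_min = 1e-4) {
  stopifnot(inherits(G, "genotype_matrix"))
  codes <- G$codes
  n <- nrow(codes)
  n_called <- colSums(!is.na(codes))
  call_rate <- n_called / n
  af <- colSums(codes, na.rm = TRUE) / (2 * pmax(n_called, 1))
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(codes)), function(j) {
    cnt <- tabulate(codes[, j] + 1L, nbins = 3L)
    hwe_test(cnt)$p
  }, numeric(1))

  no_data <- n_called == 0
  fail_maf <- !no_data & maf <= maf_min
  fail_cr <- !no_data & call_rate <= call_rate_min
  fail_hwe <- !no_data & !is.na(hwe_p) & hwe_p <= hwe_p_min
  kept <- !no_data & !fail_maf & !fail_cr & !fail_hwe

  reason <- rep("", ncol(codes))
  reason[fail_hwe] <- "hwe"
  reason[fail_cr] <- ifelse(reason[fail_cr] == "", "call_rate",
                            paste(reason[fail_cr], "call_rate", sep = ";"))
  reason[fail_maf] <- ifelse(reason[fail_maf] == "", "maf",
                             paste(reason[fail_maf], "maf", sep = ";"))
  reason[no_data] <- "no data"

  report <- data.frame(snp = colnames(codes), maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       kept = kept, reason = reason,
                       row.names = NULL)
  attr(report, "exclusions") <- c(
    no_data = sum(no_data), maf = sum(fail_maf),
    call_rate = sum(fail_cr), hwe = sum(fail_hwe),
    total_excluded = sum(!kept)
  )

  meta <- G$snp_meta
  meta$maf <- maf
  meta$call_rate <- call_rate
  meta$hwe_p <- hwe_p
  kept_G <- genotype_matrix(codes[, kept, drop = FALSE],
                            meta[kept, , drop = FALSE])
  list(genotypes = kept_G, report = report)
}
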