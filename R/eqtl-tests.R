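#' Genotype grouping for the expression ANOVA
#'
#' Samples are grouped by genotype. When fewer than `min_homozygotes`
#' samples are homozygous for the minor allele, that group is merged
#' with the heterozygotes, giving a two-group comparison; if instead
#' the heterozygote group is the rare one, the two smallest groups are
#' merged. SNPs with a single non-empty group after merging are
#' untestable.
#'
#' @param codes Per-sample additive minor-allele dosage in {0, 1, 2, NA}.
#' @param min_homozygotes Minimum minor-homozygote count to keep three
#'   groups (default 30).
#' @return List with `labels` (integer group labels 1..k, NA for
#'   missing), `n_groups`, and `testable`.
#' @export
group_genotypes <- function(codes, min_homozygotes = 30) {
  stopifnot(all(codes %in% c(0, 1, 2) | is.na(codes)))
  cnt <- tabulate(codes + 1L, nbins = 3L)  # counts for dosage 0, 1, 2
  labels <- codes + 1L
  if (cnt[3] > 0 && cnt[3] < min_homozygotes) {
    labels[labels == 3L] <- 2L            # minor homs join heterozygotes
  } else if (cnt[2] > 0 && cnt[2] < min_homozygotes && cnt[3] > 0) {
    # heterozygotes are the rare group: merge the two smallest groups
    ord <- order(cnt)
    labels[labels == ord[1]] <- ord[2]
  }
  present <- sort(unique(labels[!is.na(labels)]))
  labels <- match(labels, present)
  list(labels = labels, n_groups = length(present),
       testable = length(present) >= 2)
}

#' One-way fixed-effects ANOVA of expression on genotype groups
#'
#' Returns the F statistic, its P-value on (k-1, n-k) degrees of
#' freedom, and R-squared = SS_between / SS_total, the fraction of
#' expression variance explained by the grouping. Zero total variance
#' is reported as P = 1, R2 = 0.
#'
#' @param expr Numeric expression vector.
#' @param groups Group labels (NA excluded pairwise).
#' @return List with `f`, `p`, `r2`, `df1`, `df2`, `n`.
#' @export
anova_assoc <- function(expr, groups) {
  ok <- !is.na(expr) & !is.na(groups)
  expr <- expr[ok]; groups <- as.integer(factor(groups[ok]))
  k <- max(groups, 0L)
  n <- length(expr)
  if (k < 2 || any(tabulate(groups, k) == 0))
    stop("need at least 2 non-empty groups")
  sst <- sum(expr^2) - sum(expr)^2 / n
  if (sst <= 0) return(list(f = 0, p = 1, r2 = 0, df1 = k - 1L,
                            df2 = n - k, n = n))
  gs <- rowsum(expr, groups)
  ng <- tabulate(groups, k)
  ssb <- sum(gs^2 / ng) - sum(expr)^2 / n
  ssw <- max(sst - ssb, 0)
  df1 <- k - 1L; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE),
       r2 = ssb / sst, df1 = df1, df2 = df2, n = n)
}

#' Kruskal-Wallis confirmation test
#'
#' Rank-based robustness check applied to ANOVA hits: the
#' tie-corrected Kruskal-Wallis H with a chi-square P-value on k-1
#' degrees of freedom (via [stats::kruskal.test()]). All-tied input
#' carries no evidence and is reported as P = 1.
#'
#' @inheritParams anova_assoc
#' @return P-value.
#' @export
kw_confirm <- function(expr, groups) {
  ok <- !is.na(expr) & !is.na(groups)
  expr <- expr[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(expr)) == 1) return(1)
  kruskal.test(expr, groups)$p.value
}

#' Fisher combination of independent P-values
#'
#' `X = -2 sum(log p)` referred to chi-square with 2k degrees of
#' freedom.
#'
#' @param p Vector of independent P-values.
#' @return Combined P-value.
#' @export
fisher_combine <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Sex-stratified X-chromosome association
#'
#' X-linked SNPs are tested separately in men and women and the two
#' ANOVA P-values are combined with Fisher's method (chi-square, 4 df).
#' Hemizygous male genotypes are expected on the 0/2 dosage coding. If
#' one sex is untestable (a single genotype group), the other sex's
#' P-value is returned with a flag.
#'
#' @param expr Expression vector.
#' @param codes Dosage vector in {0, 1, 2, NA}.
#' @param sex Per-sample sex ("male"/"female" or 0/1 female coding).
#' @param min_homozygotes Passed to [group_genotypes()].
#' @return List with `p` (combined), `p_male`, `p_female`, `kw_p`
#'   (Fisher-combined per-sex Kruskal-Wallis P), `r2` (sample-size
#'   weighted mean of the per-sex R-squared), `flag` ("combined",
#'   "male_only", "female_only").
#' @export
chrx_assoc <- function(expr, codes, sex, min_homozygotes = 30) {
  female <- sex_code(sex) == 1
  one_sex <- function(sel) {
    g <- group_genotypes(codes[sel], min_homozygotes)
    if (!g$testable) return(NULL)
    a <- anova_assoc(expr[sel], g$labels)
    a$kw <- kw_confirm(expr[sel], g$labels)
    a
  }
  am <- one_sex(!female & !is.na(female))
  af <- one_sex(female & !is.na(female))
  if (is.null(am) && is.null(af)) stop("both sexes untestable")
  if (is.null(am))
    return(list(p = af$p, p_male = NA_real_, p_female = af$p,
                kw_p = af$kw, r2 = af$r2, flag = "female_only"))
  if (is.null(af))
    return(list(p = am$p, p_male = am$p, p_female = NA_real_,
                kw_p = am$kw, r2 = am$r2, flag = "male_only"))
  list(p = fisher_combine(c(am$p, af$p)),
       p_male = am$p, p_female = af$p,
       kw_p = fisher_combine(c(am$kw, af$kw)),
       r2 = (am$n * am$r2 + af$n * af$r2) / (am$n + af$n),
       flag = "combined")
}

# Additive-coding slope of expression on dosage over pairwise-complete
# samples; used to carry effect direction alongside the ANOVA result.
additive_beta <- function(expr, codes) {
  ok <- !is.na(expr) & !is.na(codes)
  if (sum(ok) < 3 || var(codes[ok]) == 0) return(NA_real_)
  cov(expr[ok], codes[ok]) / var(codes[ok])
}
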