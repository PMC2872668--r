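#' Classify an association as cis or trans
#'
#' An association is cis when the SNP lies on the gene's chromosome
#' within 1 Mb of either the 5' or 3' end of the gene, i.e. position in
#' `[start - window, end + window]` (1-based, inclusive boundaries);
#' otherwise trans.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle).
#' @param gene_chrom,gene_start,gene_end Gene interval (1-based
#'   inclusive).
#' @param window Flanking window in bp (default 1e6).
#' @return Character vector, "cis" or "trans".
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom,
                               gene_start, gene_end, window = 1e6) {
  if (any(is.na(snp_chrom)) || any(is.na(gene_chrom)))
    stop("unknown chromosome")
  ifelse(as.character(snp_chrom) == as.character(gene_chrom) &
           snp_pos >= gene_start - window & snp_pos <= gene_end + window,
         "cis", "trans")
}

# Add a cis/trans column to a scan table.
annotate_cis_trans <- function(assoc, window = 1e6) {
  assoc$cis_trans <- classify_cis_trans(assoc$chrom, assoc$pos,
                                        assoc$gene_chrom,
                                        assoc$gene_start, assoc$gene_end,
                                        window)
  assoc
}

#' Tiered eQTL summary
#'
#' For each significance tier, counts associations, eQTLs (distinct
#' genes with at least one association passing the tier) and eSNPs
#' (distinct SNPs), with cis/trans ratios for each. A gene (or SNP)
#' counts as cis at a tier if it has at least one cis association
#' there, and as trans if it has at least one trans association; both
#' are allowed simultaneously. Also reports the minimum R-squared among
#' tier associations and the median and IQR of the number of eSNPs per
#' eQTL.
#'
#' @param assoc Association table with columns `gene`, `snp`,
#'   `p_anova` (or `p`), `R2` and `cis_trans` (see
#'   [classify_cis_trans()]); typically a study-wise filtered
#'   [genome_scan()] result.
#' @param tiers Numeric vector of P-value thresholds.
#' @return data.frame of class `eqtl_summary`, one row per tier.
#' @export
summarize_eqtls <- function(assoc, tiers = c(1e-6, 1e-8, 1e-10, 5.78e-12)) {
  p <- if (!is.null(assoc$p_anova)) assoc$p_anova else assoc$p
  stopifnot(!is.null(p), !is.null(assoc$cis_trans))
  ratio <- function(a, b) if (b == 0) Inf else a / b
  rows <- lapply(tiers, function(tier) {
    sel <- assoc[p < tier, , drop = FALSE]
    if (nrow(sel) == 0)
      return(data.frame(tier = tier, min_r2 = NA_real_, n_assoc = 0L,
                        assoc_ratio = NA_real_, n_eqtl = 0L,
                        eqtl_ratio = NA_real_, n_esnp = 0L,
                        esnp_ratio = NA_real_,
                        esnps_per_eqtl_median = NA_real_,
                        esnps_per_eqtl_q1 = NA_real_,
                        esnps_per_eqtl_q3 = NA_real_))
    cis <- sel$cis_trans == "cis"
    cis_genes <- unique(sel$gene[cis]); trans_genes <- unique(sel$gene[!cis])
    cis_snps <- unique(sel$snp[cis]); trans_snps <- unique(sel$snp[!cis])
    per_eqtl <- vapply(split(sel$snp, sel$gene),
                       function(s) length(unique(s)), integer(1))
    qs <- quantile(per_eqtl, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      tier = tier, min_r2 = min(sel$R2), n_assoc = nrow(sel),
      assoc_ratio = ratio(sum(cis), sum(!cis)),
      n_eqtl = length(unique(sel$gene)),
      eqtl_ratio = ratio(length(cis_genes), length(trans_genes)),
      n_esnp = length(unique(sel$snp)),
      esnp_ratio = ratio(length(cis_snps), length(trans_snps)),
      esnps_per_eqtl_median = qs[2], esnps_per_eqtl_q1 = qs[1],
      esnps_per_eqtl_q3 = qs[3])
  })
  structure(do.call(rbind, rows), class = c("eqtl_summary", "data.frame"))
}

#' @export
print.eqtl_summary <- function(x, ...) {
  cat("eqtl_summary over", nrow(x), "significance tiers\n")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of additive dosages over
#' pairwise-complete samples. Undefined (NA) when either SNP has zero
#' variance or fewer than 2 complete pairs.
#'
#' @param G A [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared, or NA.
#' @export
ld_r2 <- function(G, snp_a, snp_b) {
  a <- G$codes[, snp_a]; b <- G$codes[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Find the best tag SNP for a lead SNP
#'
#' Returns the lead SNP itself when it is on the genotype panel
#' (r-squared 1). Otherwise, searches panel SNPs within `window` of the
#' lead position for the highest r-squared proxy, requiring
#' `r2 >= r2_min`; reference dosages for the lead SNP (`lead_codes`)
#' are needed for this off-panel search. Returns NULL when no adequate
#' tag exists.
#'
#' @param G A [genotype_matrix()].
#' @param lead_snp Lead SNP id.
#' @param lead_chrom,lead_pos Lead coordinates (needed off-panel).
#' @param lead_codes Optional dosage vector for the lead SNP, aligned
#'   with `G` samples (needed off-panel).
#' @param r2_min Minimum acceptable r-squared (default 0.8).
#' @param window Search window in bp (default 1e6).
#' @return List with `snp` and `r2`, or NULL if none.
#' @export
proxy_search <- function(G, lead_snp, lead_chrom = NULL, lead_pos = NULL,
                         lead_codes = NULL, r2_min = 0.8, window = 1e6) {
  if (lead_snp %in% G$snp_meta$snp)
    return(list(snp = lead_snp, r2 = 1.0))
  if (is.null(lead_codes) || is.null(lead_chrom) || is.null(lead_pos))
    return(NULL)
  cand <- which(G$snp_meta$chrom == lead_chrom &
                  abs(G$snp_meta$pos - lead_pos) <= window)
  if (length(cand) == 0) return(NULL)
  r2 <- vapply(cand, function(j) {
    a <- lead_codes; b <- G$codes[, j]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || var(a[ok]) == 0 || var(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])^2
  }, numeric(1))
  if (all(is.na(r2)) || max(r2, na.rm = TRUE) < r2_min) return(NULL)
  best <- cand[which.max(r2)]
  list(snp = G$snp_meta$snp[best], r2 = max(r2, na.rm = TRUE))
}

#' Flag genes probed by polymorphic sequences
#'
#' A gene's measured expression can be an artifact of differential
#' probe hybridization when a SNP lies inside the probe sequence. A
#' gene is flagged "direct" when a panel SNP falls inside its probe
#' interval, and "proxy" when a known in-probe polymorphism (possibly
#' absent from the panel) has a perfect proxy (r-squared >=
#' `r2_proxy`) among panel SNPs; otherwise it is unflagged.
#'
#' @param probes data.frame with `gene`, `chrom`, `probe_start`,
#'   `probe_end` (1-based inclusive).
#' @param G A [genotype_matrix()] (the panel).
#' @param probe_snps Optional data.frame of known in-probe
#'   polymorphisms with `gene`, `snp`; used for proxy flagging.
#' @param ld_fun Function `(snp_a, snp_b) -> r2` on the panel; default
#'   computes [ld_r2()] on `G` (both SNPs must then be on the panel).
#' @param r2_proxy Proxy threshold (default 1, perfect proxies).
#' @return data.frame with `gene`, `flag` ("direct", "proxy", ""),
#'   `snp` (the implicated SNP or NA), `r2`.
#' @export
flag_polymorphic_probes <- function(probes, G, probe_snps = NULL,
                                    ld_fun = NULL, r2_proxy = 1) {
  stopifnot(all(c("gene", "chrom", "probe_start", "probe_end") %in%
                  names(probes)))
  if (is.null(ld_fun))
    ld_fun <- function(a, b) ld_r2(G, a, b)
  out <- data.frame(gene = probes$gene, flag = "", snp = NA_character_,
                    r2 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(probes))) {
    inside <- which(G$snp_meta$chrom == probes$chrom[i] &
                      G$snp_meta$pos >= probes$probe_start[i] &
                      G$snp_meta$pos <= probes$probe_end[i])
    if (length(inside) > 0) {
      out$flag[i] <- "direct"
      out$snp[i] <- G$snp_meta$snp[inside[1]]
      out$r2[i] <- 1
      next
    }
    if (is.null(probe_snps)) next
    known <- probe_snps$snp[probe_snps$gene == probes$gene[i]]
    known <- setdiff(known, G$snp_meta$snp)  # off-panel in-probe SNPs
    best_r2 <- NA_real_; best_snp <- NA_character_
    for (k in known) {
      near <- which(G$snp_meta$chrom == probes$chrom[i] &
                      abs(G$snp_meta$pos - probes$probe_start[i]) <= 1e6)
      for (j in near) {
        r2 <- ld_fun(k, G$snp_meta$snp[j])
        if (!is.na(r2) && (is.na(best_r2) || r2 > best_r2)) {
          best_r2 <- r2; best_snp <- G$snp_meta$snp[j]
        }
      }
    }
    if (!is.na(best_r2) && best_r2 >= r2_proxy) {
      out$flag[i] <- "proxy"; out$snp[i] <- best_snp; out$r2[i] <- best_r2
    }
  }
  out
}

#' Replication of an external cis-eQTL list
#'
#' For each external eQTL whose gene is expressed internally, the eQTL
#' replicates when the best internal cis P-value for that gene is below
#' `threshold` (a per-gene Bonferroni level). External genes absent
#' from the internal panel are excluded from the denominator. Results
#' are stratified by external significance tier when external P-values
#' are supplied.
#'
#' @param external data.frame with `gene` and optionally `p`
#'   (the external study's P-value).
#' @param internal Annotated association table (needs `gene`,
#'   `p_anova` or `p`, `cis_trans`).
#' @param threshold Internal replication threshold (default 3.9e-6,
#'   Bonferroni for ~12.8k expressions).
#' @param tier_breaks Breaks on -log10 external P for stratification.
#' @return List with `overall` (percent replicated, numerator,
#'   denominator) and `by_tier` data.frame. Zero matched genes yields
#'   zero denominators with a warning.
#' @export
replication_overlap <- function(external, internal, threshold = 3.9e-6,
                                tier_breaks = c(0, 8, 10, 15, 20, 25, Inf)) {
  stopifnot(!is.null(external$gene))
  p_int <- if (!is.null(internal$p_anova)) internal$p_anova else internal$p
  cis <- internal[internal$cis_trans == "cis", , drop = FALSE]
  p_int <- p_int[internal$cis_trans == "cis"]
  best_cis <- tapply(p_int, cis$gene, min)
  matched <- external[external$gene %in% names(best_cis), , drop = FALSE]
  if (nrow(matched) == 0) {
    warning("no external genes matched the internal panel")
    return(list(overall = data.frame(percent = NA_real_, replicated = 0L,
                                     total = 0L),
                by_tier = NULL))
  }
  rep_flag <- best_cis[matched$gene] < threshold
  overall <- data.frame(percent = 100 * mean(rep_flag),
                        replicated = sum(rep_flag),
                        total = length(rep_flag))
  by_tier <- NULL
  if (!is.null(matched$p)) {
    tier <- cut(-log10(matched$p), breaks = tier_breaks, right = FALSE)
    by_tier <- do.call(rbind, lapply(levels(tier), function(lv) {
      sel <- tier == lv
      data.frame(tier = lv, total = sum(sel),
                 replicated = sum(rep_flag[sel]),
                 percent = if (sum(sel)) 100 * mean(rep_flag[sel])
                           else NA_real_)
    }))
  }
  list(overall = overall, by_tier = by_tier)
}
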