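#' Random split into screening and validation halves
#'
#' Disjoint, exhaustive halves with sizes differing by at most one;
#' deterministic given the seed.
#'
#' @param sample_ids Character vector of sample ids (n >= 4).
#' @param seed Seed for the split.
#' @return List with `screen` and `validation` id vectors.
#' @export
split_half <- function(sample_ids, seed) {
  n <- length(sample_ids)
  stopifnot(n >= 4)
  set.seed(derive_seed(seed, "split_half"))
  idx <- sample.int(n, floor(n / 2))
  list(screen = sample_ids[sort(idx)],
       validation = sample_ids[sort(setdiff(seq_len(n), idx))])
}

#' Screening-half univariate filter and forward stepwise selection
#'
#' First screens every expression trait for covariate-adjusted
#' association with the risk factor at `screen_p` (Bonferroni scale for
#' the transcriptome). The surviving candidates then enter a pure
#' forward stepwise regression with the risk factor as dependent
#' variable: at each step the candidate with the smallest partial-F
#' P-value is added if it is below `p_enter`, otherwise selection
#' stops. When the screen passes more than `max_candidates` genes, the
#' `max_candidates` smallest P-values are kept (guards the stepwise in
#' pathological simulations).
#'
#' @param E Samples-by-genes expression matrix (screening half).
#' @param rf Risk-factor vector (screening half).
#' @param Z Covariate design matrix including intercept.
#' @param screen_p Univariate screen threshold (default 3.9e-6).
#' @param p_enter Stepwise entry threshold (default 0.01).
#' @param max_candidates Candidate cap (default 100).
#' @return Character vector of selected genes in entry order.
#' @export
screen_stepwise <- function(E, rf, Z, screen_p = 3.9e-6, p_enter = 0.01,
                            max_candidates = 100) {
  uni <- partial_assoc(E, rf, Z)
  cand <- uni[uni$p < screen_p, , drop = FALSE]
  if (nrow(cand) == 0) return(character())
  cand <- cand[order(cand$p), , drop = FALSE]
  if (nrow(cand) > max_candidates)
    cand <- cand[seq_len(max_candidates), , drop = FALSE]

  qz <- qr(Z)
  ry <- qr.resid(qz, rf)
  C <- qr.resid(qz, E[, cand$gene, drop = FALSE])
  ss0 <- colSums(C^2)
  n <- length(rf); p_base <- ncol(Z)
  selected <- character(); remaining <- seq_len(ncol(C))
  repeat {
    df2 <- n - p_base - length(selected) - 1
    if (df2 < 2 || length(remaining) == 0) break
    ssy <- sum(ry^2)
    ssc <- colSums(C[, remaining, drop = FALSE]^2)
    cross <- as.vector(crossprod(C[, remaining, drop = FALSE], ry))
    # candidates numerically collinear with selected predictors
    alive <- ssc > 1e-10 * ss0[remaining] & ssy > 0
    r <- ifelse(alive, cross / sqrt(ssc * ssy), 0)
    r <- pmin(pmax(r, -1), 1)
    t <- r * sqrt(df2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(abs(t), df2, lower.tail = FALSE)
    p[!alive] <- 1
    best <- which.min(p)
    if (p[best] >= p_enter) break
    j <- remaining[best]
    u <- C[, j]
    selected <- c(selected, colnames(C)[j])
    remaining <- setdiff(remaining, j)
    uu <- sum(u^2)
    ry <- ry - u * sum(u * ry) / uu
    if (length(remaining))
      C[, remaining] <- C[, remaining, drop = FALSE] -
        u %*% (crossprod(u, C[, remaining, drop = FALSE]) / uu)
  }
  selected
}

#' Joint validation of screened genes
#'
#' Multiple regression of the risk factor on covariates plus all
#' selected genes in the validation half: per-gene t-test P-values and
#' a global nested-model F-test of the full model against the
#' covariates-only model. An empty selection is recorded with global
#' P = 1 by convention.
#'
#' @param E Samples-by-genes expression matrix (validation half).
#' @param selected Character vector of gene names.
#' @param rf Risk-factor vector (validation half).
#' @param Z Covariate design matrix including intercept.
#' @return List with `per_gene` (data.frame gene, beta, t, p) and
#'   `global_p`.
#' @export
validate_joint <- function(E, selected, rf, Z) {
  if (length(selected) == 0)
    return(list(per_gene = NULL, global_p = 1))
  n <- length(rf)
  if (ncol(Z) + length(selected) >= n)
    stop("more predictors than samples in the validation half")
  X <- cbind(Z, E[, selected, drop = FALSE])
  fit <- lm.fit(X, rf)
  if (fit$rank < ncol(X)) {
    # aliased gene columns: fall back to lm for proper NA handling
    dat <- data.frame(rf = rf, as.data.frame(X[, -1, drop = FALSE]))
    lmfit <- lm(rf ~ ., data = dat)
    cf <- summary(lmfit)$coefficients
    idx <- match(make.names(selected), rownames(cf))
    per_gene <- data.frame(gene = selected, beta = cf[idx, 1],
                           t = cf[idx, 3], p = cf[idx, 4],
                           row.names = NULL)
    lm0 <- lm(rf ~ ., data = dat[, c("rf", colnames(Z)[-1]), drop = FALSE])
    global_p <- anova(lm0, lmfit)[2, "Pr(>F)"]
    return(list(per_gene = per_gene, global_p = global_p))
  }
  rss1 <- sum(fit$residuals^2)
  df2 <- n - ncol(X)
  sigma2 <- rss1 / df2
  XtXinv_diag <- diag(chol2inv(qr.R(fit$qr)))
  se <- sqrt(sigma2 * XtXinv_diag)
  tval <- fit$coefficients / se
  pval <- 2 * pt(abs(tval), df2, lower.tail = FALSE)
  gi <- ncol(Z) + seq_along(selected)
  per_gene <- data.frame(gene = selected, beta = fit$coefficients[gi],
                         t = tval[gi], p = pval[gi], row.names = NULL)
  fit0 <- lm.fit(Z, rf)
  rss0 <- sum(fit0$residuals^2)
  k <- length(selected)
  f <- ((rss0 - rss1) / k) / sigma2
  global_p <- pf(f, k, df2, lower.tail = FALSE)
  list(per_gene = per_gene, global_p = global_p)
}

#' Split-half stability selection of independent expression correlates
#'
#' Repeats the screening/validation procedure `n_reps` times: the
#' cohort is randomly halved; the screening half runs the univariate
#' filter plus forward stepwise selection ([screen_stepwise()]); the
#' genes selected there are jointly re-tested in the validation half
#' ([validate_joint()]). A gene counts in a replicate when it is
#' selected at screening AND its validation P-value is below `p_valid`.
#' Genes counted in more than `freq_min` of the replicates are
#' reported, with their selection frequency and the sign of the
#' (validation) association, together with the median and range of the
#' global P-value across replicates.
#'
#' @param expr An [expression_matrix()] or samples-by-genes matrix.
#' @param covariates Covariate table.
#' @param rf Risk factor name (see [default_schemes()]).
#' @param n_reps Number of split-half replicates (default 250).
#' @param freq_min Reporting frequency threshold (default 0.25,
#'   strict).
#' @param p_valid Per-gene validation threshold (default 0.01).
#' @param screen_p,p_enter,max_candidates Passed to
#'   [screen_stepwise()].
#' @param schemes Adjustment schemes.
#' @param master_seed Master seed; replicate r uses `master_seed + r`.
#' @return Object of class `stability_result`: `reported` (gene,
#'   frequency, sign), `frequencies` (all ever-counted genes),
#'   `global_p` (per replicate), and the call parameters.
#' @export
stability_select <- function(expr, covariates, rf, n_reps = 250,
                             freq_min = 0.25, p_valid = 0.01,
                             screen_p = 3.9e-6, p_enter = 0.01,
                             max_candidates = 100,
                             schemes = default_schemes(),
                             master_seed = 1L) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  covs <- schemes[[rf]]; if (is.null(covs)) covs <- c("age", "sex")
  x_all <- rf_value(covariates, rf)
  Z_all <- scheme_matrix(covariates, covs)
  ok <- complete.cases(cbind(x_all, Z_all))
  values <- values[ok, , drop = FALSE]
  x_all <- x_all[ok]; Z_all <- Z_all[ok, , drop = FALSE]
  ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))

  counts <- numeric(ncol(values)); names(counts) <- colnames(values)
  sign_sum <- counts
  global_p <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    halves <- split_half(ids, seed = master_seed + r)
    ia <- match(halves$screen, ids); ib <- match(halves$validation, ids)
    sel <- screen_stepwise(values[ia, , drop = FALSE], x_all[ia],
                           Z_all[ia, , drop = FALSE],
                           screen_p = screen_p, p_enter = p_enter,
                           max_candidates = max_candidates)
    val <- validate_joint(values[ib, , drop = FALSE], sel, x_all[ib],
                          Z_all[ib, , drop = FALSE])
    global_p[r] <- val$global_p
    if (!is.null(val$per_gene)) {
      hit <- val$per_gene[val$per_gene$p < p_valid, , drop = FALSE]
      counts[hit$gene] <- counts[hit$gene] + 1
      sign_sum[hit$gene] <- sign_sum[hit$gene] + sign(hit$beta)
    }
  }
  freq <- counts / n_reps
  ever <- freq[freq > 0]
  rep_sel <- freq > freq_min
  reported <- data.frame(gene = names(freq)[rep_sel],
                         frequency = unname(freq[rep_sel]),
                         sign = sign(unname(sign_sum[rep_sel])),
                         row.names = NULL)
  reported <- reported[order(-reported$frequency), , drop = FALSE]
  rownames(reported) <- NULL
  structure(list(rf = rf, reported = reported,
                 frequencies = sort(ever, decreasing = TRUE),
                 global_p = global_p,
                 global_p_median = median(global_p),
                 global_p_range = range(global_p),
                 n_reps = n_reps, freq_min = freq_min,
                 p_valid = p_valid, master_seed = master_seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result for", x$rf, "over", x$n_reps, "replicates\n")
  cat(sprintf("  global P median %.3g (range %.3g - %.3g)\n",
              x$global_p_median, x$global_p_range[1], x$global_p_range[2]))
  if (nrow(x$reported)) {
    cat("  reported genes (frequency >", x$freq_min, "):\n")
    print(x$reported)
  } else cat("  no gene above the reporting frequency\n")
  invisible(x)
}
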