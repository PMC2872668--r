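# Per-sex reference distribution of the cohort's risk factors:
# mean and SD of each quantitative factor (CRP on the square-root
# scale), plus current-smoking prevalence and the male fraction.
ghs_reference <- list(
  p_male = 760 / 1490,
  smoking = c(male = 0.168, female = 0.155),
  quantitative = data.frame(
    rf = c("age", "bmi", "hdl", "ldl", "tg", "sbp", "dbp",
           "sqrt_crp", "glucose"),
    mean_male = c(56.4, 27.6, 54.4, 133.7, 143.2, 135.8, 85.2,
                  1.509, 97.8),
    sd_male = c(10.6, 3.9, 14.9, 36.1, 97.5, 16.7, 9.6, 0.818, 18.5),
    mean_female = c(53.9, 26.2, 69.2, 133.0, 114.4, 128.5, 81.2,
                    1.545, 91.8),
    sd_female = c(11.2, 5.1, 17.8, 36.8, 56.8, 18.2, 9.5, 0.743, 15.4)
  )
)

#' Simulate cohort risk factors
#'
#' Draws a per-sample covariate table from the reference cohort
#' distribution: sex is Bernoulli at the cohort male fraction
#' (760/1490), quantitative factors are Gaussian with the per-sex
#' reference means and SDs, current smoking is Bernoulli at the per-sex
#' prevalence, and CRP is generated on the square-root scale (a
#' Gaussian draw `s` gives `crp = s^2`), so `sqrt_crp` follows the
#' reference mean/SD up to folding of the rare negative draws.
#'
#' @param config A [sim_config()] (only `n_samples` and `seed` are used).
#' @return data.frame with columns `sample_id`, `sex`, `age`, `bmi`,
#'   `hdl`, `ldl`, `tg`, `sbp`, `dbp`, `smoking`, `crp`, `sqrt_crp`,
#'   `glucose`.
#' @export
sim_risk_factors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ids <- sim_ids(config)
  set.seed(derive_seed(config$seed, "risk_factors"))

  male <- runif(n) < ghs_reference$p_male
  sex <- ifelse(male, "male", "female")
  q <- ghs_reference$quantitative
  draw <- function(rf) {
    i <- match(rf, q$rf)
    m <- ifelse(male, q$mean_male[i], q$mean_female[i])
    s <- ifelse(male, q$sd_male[i], q$sd_female[i])
    rnorm(n, m, s)
  }
  out <- data.frame(
    sample_id = ids$samples, sex = sex,
    age = draw("age"), bmi = draw("bmi"), hdl = draw("hdl"),
    ldl = draw("ldl"), tg = draw("tg"), sbp = draw("sbp"),
    dbp = draw("dbp"),
    smoking = as.integer(runif(n) < ifelse(male,
                                           ghs_reference$smoking["male"],
                                           ghs_reference$smoking["female"])),
    row.names = NULL
  )
  s_crp <- draw("sqrt_crp")
  out$crp <- s_crp^2
  out$sqrt_crp <- abs(s_crp)
  out$glucose <- draw("glucose")
  out
}
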