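#' Prepare the covariate table for association analysis
#'
#' Applies the cohort's covariate conventions: smoking status collapsed
#' to a binary indicator (never and former smokers are non-smokers;
#' occasional and regular smokers are smokers), and a square-root
#' transform of CRP added as `sqrt_crp` to remove positive skewness.
#' Blood-pressure values are taken as given (averaging of repeated
#' sphygmomanometer readings happens upstream of this package).
#'
#' @param raw data.frame with at least `crp` (mg/L, non-negative) and
#'   either a binary `smoking` column or a character `smoking_status`
#'   column with values among "never", "former", "occasional",
#'   "regular"/"smoker".
#' @return The table with `smoking` in {0, 1} and `sqrt_crp` added.
#' @export
prepare_covariates <- function(raw) {
  stopifnot(is.data.frame(raw))
  out <- raw
  if (!is.null(out$smoking_status)) {
    status <- tolower(as.character(out$smoking_status))
    smoker <- status %in% c("occasional", "regular", "smoker",
                            "occasional smoker", "current smoker")
    nonsmoker <- status %in% c("never", "former", "never smoker",
                               "former smoker", "non-smoker")
    if (any(!smoker & !nonsmoker & !is.na(status)))
      stop("unrecognized smoking status: ",
           paste(unique(status[!smoker & !nonsmoker]), collapse = ", "))
    out$smoking <- ifelse(is.na(status), NA_integer_, as.integer(smoker))
  }
  if (!is.null(out$smoking) && !all(out$smoking %in% c(0, 1, NA)))
    stop("smoking must be binary")
  if (!is.null(out$crp)) {
    if (any(out$crp < 0, na.rm = TRUE)) stop("negative CRP")
    out$sqrt_crp <- sqrt(out$crp)
  }
  out
}

# Numeric coding of sex used throughout the models: female = 1, male = 0,
# so a positive coefficient means higher in women.
sex_code <- function(sex) {
  if (is.numeric(sex)) {
    stopifnot(all(sex %in% c(0, 1, NA)))
    return(sex)
  }
  s <- tolower(as.character(sex))
  stopifnot(all(s %in% c("male", "female", NA)))
  ifelse(is.na(s), NA_real_, as.numeric(s == "female"))
}
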