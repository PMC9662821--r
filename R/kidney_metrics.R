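## Kidney-function metrics: IDMS calibration, the 2009 CKD-EPI creatinine
## equation, and cohort eligibility filtering.

#' Calibrate serum creatinine to IDMS-standardized values
#'
#' Creatinine measured with assays that were not standardized to
#' isotope-dilution mass spectrometry (IDMS) is multiplied by 0.95;
#' standardized measurements are returned unchanged.
#'
#' @param creatinine Serum creatinine in mg/dL (positive).
#' @param idms_standardized Logical (recycled): was the assay IDMS-standardized?
#' @return Calibrated creatinine in mg/dL.
#' @examples
#' idms_calibrate(1.0, FALSE)  # 0.95
#' idms_calibrate(1.0, TRUE)   # 1.00
#' @export
idms_calibrate <- function(creatinine, idms_standardized) {
  assert_that(all(is.finite(creatinine)) && all(creatinine > 0),
              "creatinine must be positive and finite")
  assert_that(is.logical(idms_standardized) && !anyNA(idms_standardized),
              "idms_standardized must be TRUE/FALSE")
  ifelse(idms_standardized, creatinine, creatinine * 0.95)
}

#' Convert creatinine from umol/L to mg/dL
#'
#' @param x Creatinine in umol/L.
#' @return Creatinine in mg/dL (divides by 88.4).
#' @export
creatinine_umol_to_mgdl <- function(x) x / 88.4

#' Estimated glomerular filtration rate (2009 CKD-EPI creatinine equation)
#'
#' Computes eGFR (mL/min/1.73m^2) from IDMS-calibrated serum creatinine, sex
#' and age:
#' \deqn{141 \times \min(Scr/\kappa, 1)^{\alpha} \times \max(Scr/\kappa, 1)^{-1.209}
#'   \times 0.993^{age} \times 1.018[\mathrm{female}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and \eqn{\alpha = -0.329}
#' (female) / -0.411 (male). The race coefficient is omitted: the analyses this
#' package supports are restricted to single-ancestry cohorts.
#'
#' @param creatinine Serum creatinine, mg/dL, IDMS-calibrated, positive.
#' @param sex Character vector, "male" or "female" (recycled).
#' @param age Age in years, positive.
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' ckd_epi_2009(1.0, "male", 57)
#' ckd_epi_2009(0.7, "female", 40)
#' @export
ckd_epi_2009 <- function(creatinine, sex, age) {
  assert_that(all(is.finite(creatinine)) && all(creatinine > 0),
              "creatinine must be positive and finite")
  assert_that(all(is.finite(age)) && all(age > 0), "age must be positive")
  sex <- as.character(sex)
  assert_that(all(sex %in% c("male", "female")),
              "sex must be 'male' or 'female'")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

#' Invert the 2009 CKD-EPI creatinine equation
#'
#' Returns the serum creatinine (mg/dL) that yields a given eGFR for a
#' participant of given sex and age. Used by the cohort simulator to emit
#' creatinine consistent with the simulated eGFR.
#'
#' @param egfr Target eGFR, mL/min/1.73m^2, positive.
#' @param sex "male"/"female".
#' @param age Years.
#' @return Creatinine in mg/dL.
#' @export
ckd_epi_2009_invert <- function(egfr, sex, age) {
  assert_that(all(is.finite(egfr)) && all(egfr > 0), "egfr must be positive")
  sex <- as.character(sex)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  a <- 141 * 0.993^age * ifelse(female, 1.018, 1)  # eGFR at Scr == kappa
  ## below a: high-creatinine branch (exponent -1.209); above a: low branch
  ifelse(egfr < a,
         kappa * (egfr / a)^(-1 / 1.209),
         kappa * (egfr / a)^(1 / alpha))
}

## Eligibility criteria, in the order used for first-failure attribution.
eligibility_criteria <- c(
  required_fields = "missing age, sex, creatinine or diabetes status",
  age_range       = "age outside 30-80 years",
  egfr_range      = "eGFR >= 300",
  history         = "history of CVD or diabetes",
  risk_factors    = "incomplete smoking/SBP/cholesterol/HDL/BMI",
  followup        = "less than 1 year of follow-up"
)

#' Apply cohort eligibility criteria
#'
#' Retains participants who (in attribution order): have recorded age, sex,
#' creatinine and diabetes status; are aged 30-80 years inclusive; have
#' eGFR < 300; have no history of CVD or diabetes; have complete smoking
#' status, systolic blood pressure, total and HDL cholesterol and BMI; and
#' have at least 1 year of follow-up. Each excluded participant is attributed
#' to the first criterion they fail.
#'
#' @param records Data frame with columns `age`, `sex`, `creatinine`,
#'   `history_diabetes`, `history_cvd`, `egfr`, `smoking`, `sbp`, `tchol`,
#'   `hdl`, `bmi`, `time`.
#' @return An object of class `eligibility_result`: list with `records`
#'   (retained rows), `tally` (named integer vector of first-failure counts),
#'   `n_input`, `n_retained`.
#' @export
eligibility_filter <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("age", "sex", "creatinine", "history_diabetes", "history_cvd",
            "egfr", "smoking", "sbp", "tchol", "hdl", "bmi", "time")
  missing_cols <- setdiff(need, names(records))
  assert_that(length(missing_cols) == 0,
              "records lacks columns: %s", paste(missing_cols, collapse = ", "))
  n <- nrow(records)
  fails <- matrix(FALSE, n, length(eligibility_criteria),
                  dimnames = list(NULL, names(eligibility_criteria)))
  if (n > 0) {
    fails[, "required_fields"] <- is.na(records$age) | is.na(records$sex) |
      is.na(records$creatinine) | is.na(records$history_diabetes)
    fails[, "age_range"] <- !is.na(records$age) &
      (records$age < 30 | records$age > 80)
    fails[, "egfr_range"] <- is.na(records$egfr) | records$egfr >= 300
    fails[, "history"] <- (!is.na(records$history_cvd) & records$history_cvd) |
      (!is.na(records$history_diabetes) & records$history_diabetes)
    fails[, "risk_factors"] <- !complete.cases(
      records[, c("smoking", "sbp", "tchol", "hdl", "bmi")])
    fails[, "followup"] <- is.na(records$time) | records$time < 1
  }
  any_fail <- rowSums(fails) > 0
  first_fail <- rep(NA_integer_, n)
  for (j in seq_along(eligibility_criteria)) {
    sel <- fails[, j] & is.na(first_fail)
    first_fail[sel] <- j
  }
  tally <- setNames(integer(length(eligibility_criteria)),
                    names(eligibility_criteria))
  if (any(any_fail)) {
    tb <- tabulate(first_fail[any_fail], nbins = length(eligibility_criteria))
    tally[] <- as.integer(tb)
  }
  out <- list(records = records[!any_fail, , drop = FALSE],
              tally = tally, n_input = n, n_retained = sum(!any_fail))
  class(out) <- "eligibility_result"
  out
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("Eligibility filter: %d of %d participants retained\n",
              x$n_retained, x$n_input))
  for (k in names(x$tally)) {
    if (x$tally[[k]] > 0)
      cat(sprintf("  excluded (%s): %d\n", eligibility_criteria[[k]],
                  x$tally[[k]]))
  }
  invisible(x)
}
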