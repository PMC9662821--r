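## Observational dose-response: stratified Cox models (optionally
## Prentice-weighted for case-cohort designs) and fractional-polynomial
## curves anchored at a reference eGFR of 90.

#' @importFrom survival coxph Surv strata coxph.control
NULL

build_cox_formula <- function(response, covariates, strata_cols) {
  rhs <- paste(c(covariates,
                 if (length(strata_cols))
                   sprintf("strata(%s)", paste(strata_cols, collapse = ", "))),
               collapse = " + ")
  as.formula(paste(response, "~", rhs))
}

#' Stratified Cox proportional-hazards model
#'
#' Fits a Cox model by stratified partial likelihood with Breslow tie
#' handling. Strata (default sex and study center) contribute separate
#' baseline hazards; strata without events contribute nothing.
#'
#' @param data Data frame with `time` and `event` columns plus covariates.
#' @param covariates Character vector of model terms (may include expressions
#'   such as `"I(age^2)"`).
#' @param strata_cols Character vector of stratification columns
#'   (default `c("sex", "center")`); use `character(0)` for none.
#' @param robust Logical: also compute the sandwich (robust) variance.
#' @return Object of class `cox_fit`: list with `coef`, `vcov`, `loglik`,
#'   `n`, `nevent`, `flags` (e.g. zero-variance covariates reported as
#'   coefficient 0 with `infinite_variance`), and the underlying `coxph` fit.
#' @export
fit_stratified_cox <- function(data, covariates,
                               strata_cols = c("sex", "center"),
                               robust = FALSE) {
  stopifnot(is.data.frame(data))
  assert_that(all(c("time", "event") %in% names(data)),
              "data needs 'time' and 'event' columns")
  assert_that(sum(data$event) > 0, "no events in data")
  ## zero-variance covariates: no contrast; report 0 with a flag
  flags <- character(0)
  plain <- covariates[covariates %in% names(data)]
  degenerate <- plain[vapply(plain, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) < 2
  }, TRUE)]
  use_cov <- setdiff(covariates, degenerate)
  if (length(degenerate)) flags <- c(flags, "infinite_variance")
  assert_that(length(use_cov) > 0 || length(degenerate) > 0,
              "no covariates supplied")
  if (length(use_cov) == 0) {
    cf <- setNames(rep(0, length(degenerate)), degenerate)
    out <- list(coef = cf, vcov = diag(Inf, length(cf)), loglik = NA_real_,
                n = nrow(data), nevent = sum(data$event),
                flags = flags, fit = NULL,
                degenerate = degenerate)
    class(out) <- "cox_fit"
    return(out)
  }
  f <- build_cox_formula("Surv(time, event)", use_cov, strata_cols)
  fit <- coxph(f, data = data, ties = "breslow", robust = robust,
               control = coxph.control(iter.max = 50))
  if (any(is.na(coef(fit)))) flags <- c(flags, "not_estimable")
  if (fit$iter >= 50) flags <- c(flags, "non_convergence")
  ## monotone likelihood shows up as huge coefficients/SEs
  if (any(abs(coef(fit)) > 15, na.rm = TRUE)) flags <- c(flags, "possible_separation")
  cf <- coef(fit)
  V <- if (robust) fit$var else vcov(fit)
  if (length(degenerate)) {
    cf <- c(cf, setNames(rep(0, length(degenerate)), degenerate))
  }
  out <- list(coef = cf, vcov = V, loglik = fit$loglik[length(fit$loglik)],
              n = fit$n, nevent = fit$nevent, flags = flags, fit = fit,
              degenerate = degenerate)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox fit: n = %d, events = %d\n", x$n, x$nevent))
  print(x$coef)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Prentice-weighted Cox model for case-cohort data
#'
#' Fits the Prentice pseudolikelihood for a case-cohort design: subcohort
#' members are at risk from entry; cases outside the subcohort enter the risk
#' set only just before their own failure time. Implemented via the
#' counting-process representation with an entry offset smaller than the
#' smallest gap between distinct event times; variance is the sandwich
#' (robust) estimate clustered on participant.
#'
#' @param data Data frame with `time`, `event`, a logical `subcohort` column
#'   and an `id` column.
#' @param covariates Character vector of model terms.
#' @param strata_cols Stratification columns (default sex and center).
#' @return A `cox_fit` (robust variance in `vcov`).
#' @export
prentice_weighted_cox <- function(data, covariates,
                                  strata_cols = c("sex", "center")) {
  stopifnot(is.data.frame(data))
  assert_that(all(c("time", "event", "subcohort", "id") %in% names(data)),
              "data needs 'time', 'event', 'subcohort', 'id' columns")
  assert_that(sum(data$event) > 0, "no events in data")
  assert_that(any(data$subcohort & data$event == 0),
              "case-cohort design needs subcohort non-cases")
  et <- sort(unique(data$time[data$event == 1]))
  eps <- if (length(et) > 1) min(diff(et)) / 2 else min(et) / 2
  eps <- min(eps, min(data$time[data$time > 0]) / 2)
  start <- ifelse(data$subcohort, 0, pmax(data$time - eps, 0))
  d <- data
  d$.start <- start
  keep <- d$subcohort | d$event == 1  # non-subcohort non-cases drop out
  d <- d[keep, , drop = FALSE]
  rhs <- paste(c(covariates,
                 if (length(strata_cols))
                   sprintf("strata(%s)", paste(strata_cols, collapse = ", ")),
                 "cluster(id)"),
               collapse = " + ")
  f <- as.formula(paste("Surv(.start, time, event) ~", rhs))
  ## timefix would round the entry offset back onto the failure time
  fit <- coxph(f, data = d, ties = "breslow",
               control = coxph.control(iter.max = 50, timefix = FALSE))
  flags <- character(0)
  if (any(is.na(coef(fit)))) flags <- c(flags, "not_estimable")
  out <- list(coef = coef(fit), vcov = fit$var,
              loglik = fit$loglik[length(fit$loglik)],
              n = fit$n, nevent = fit$nevent, flags = flags, fit = fit,
              degenerate = character(0))
  class(out) <- "cox_fit"
  out
}

## ---------------------------------------------------------------------------
## Fractional polynomials

fp_power_set <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial basis
#'
#' Transforms a positive exposure by fractional-polynomial powers from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 denotes the natural log). A repeated
#' power p contributes `x^p` and `x^p * log(x)`.
#'
#' @param x Positive numeric vector (already rescaled if desired).
#' @param powers Numeric vector of length 1 or 2.
#' @return Matrix with one column per FP term.
#' @export
fp_transform <- function(x, powers) {
  assert_that(all(x > 0), "fractional polynomials require positive exposure")
  assert_that(length(powers) %in% 1:2, "powers must have length 1 or 2")
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) {
    m <- cbind(one(powers))
    colnames(m) <- paste0("fp", 1)
    return(m)
  }
  p <- sort(powers)
  if (p[1] == p[2]) {
    m <- cbind(one(p[1]), one(p[1]) * log(x))
  } else {
    m <- cbind(one(p[1]), one(p[2]))
  }
  colnames(m) <- paste0("fp", 1:2)
  m
}

fp_candidates <- function() {
  fp1 <- lapply(fp_power_set, function(p) p)
  fp2 <- list()
  for (i in seq_along(fp_power_set)) for (j in i:length(fp_power_set)) {
    fp2[[length(fp2) + 1]] <- c(fp_power_set[i], fp_power_set[j])
  }
  list(fp1 = fp1, fp2 = fp2)
}

fit_fp_one <- function(data, x, powers, covariates, strata_cols) {
  B <- fp_transform(x, powers)
  d <- cbind(data, as.data.frame(B))
  f <- build_cox_formula("Surv(time, event)",
                         c(colnames(B), covariates), strata_cols)
  fit <- coxph(f, data = d, ties = "breslow",
               control = coxph.control(iter.max = 50))
  list(fit = fit, powers = powers,
       deviance = -2 * fit$loglik[length(fit$loglik)])
}

#' Fit a fractional-polynomial Cox dose-response model
#'
#' Searches degree-2 fractional polynomials (36 unordered power pairs,
#' including repeated powers) and degree-1 models over the standard power
#' set, under a stratified Cox model with Breslow ties. Model selection is a
#' closed test on the partial-likelihood deviance: the best FP2 is kept only
#' if it improves on the best FP1 by at least 3.84; the best FP1 is kept only
#' if it improves on the linear model (power 1) by at least 3.84. The
#' exposure is rescaled by 1/10 before transformation for numerical
#' stability; reported curves undo the rescaling.
#'
#' @param data Data frame with `time`, `event`, exposure and covariates.
#' @param exposure Name of the (strictly positive) exposure column,
#'   default `"egfr"`.
#' @param covariates Character vector of adjustment terms.
#' @param strata_cols Stratification columns.
#' @param powers Optional forced powers (length 1 or 2); skips selection.
#' @param rescale Divisor applied to the exposure before transformation
#'   (default 10).
#' @param reference Reference exposure for curve anchoring (default 90).
#' @return Object of class `fp_model`: `powers`, `degree`, `coef` and `vcov`
#'   restricted to the FP terms, `deviance`, `selection` (deviance table),
#'   `rescale`, `reference`, and the full `cox_fit`.
#' @export
fit_fractional_polynomial <- function(data, exposure = "egfr",
                                      covariates = character(0),
                                      strata_cols = c("sex", "center"),
                                      powers = NULL, rescale = 10,
                                      reference = 90) {
  stopifnot(is.data.frame(data))
  x_raw <- data[[exposure]]
  assert_that(!is.null(x_raw), "exposure column '%s' not found", exposure)
  assert_that(all(is.finite(x_raw)) && all(x_raw > 0),
              "all exposures must be positive")
  x <- x_raw / rescale
  selection <- NULL
  if (is.null(powers)) {
    cand <- fp_candidates()
    fits1 <- lapply(cand$fp1, fit_fp_one, data = data, x = x,
                    covariates = covariates, strata_cols = strata_cols)
    fits2 <- lapply(cand$fp2, fit_fp_one, data = data, x = x,
                    covariates = covariates, strata_cols = strata_cols)
    dev1 <- vapply(fits1, `[[`, 0, "deviance")
    dev2 <- vapply(fits2, `[[`, 0, "deviance")
    best1 <- fits1[[which.min(dev1)]]
    best2 <- fits2[[which.min(dev2)]]
    linear <- fits1[[which(fp_power_set == 1)]]
    ## closed test, preferring fewer terms
    chosen <- if (best1$deviance - best2$deviance >= 3.84) best2 else {
      if (linear$deviance - best1$deviance >= 3.84) best1 else linear
    }
    selection <- data.frame(
      model = c("best_fp2", "best_fp1", "linear"),
      powers = c(paste(best2$powers, collapse = ","),
                 paste(best1$powers, collapse = ","), "1"),
      deviance = c(best2$deviance, best1$deviance, linear$deviance))
  } else {
    chosen <- fit_fp_one(data, x, powers, covariates, strata_cols)
  }
  fit <- chosen$fit
  fp_terms <- grep("^fp[12]$", names(coef(fit)), value = TRUE)
  out <- list(powers = sort(chosen$powers), degree = length(chosen$powers),
              coef = coef(fit)[fp_terms],
              vcov = vcov(fit)[fp_terms, fp_terms, drop = FALSE],
              deviance = chosen$deviance, selection = selection,
              rescale = rescale, reference = reference, fit = fit)
  class(out) <- "fp_model"
  out
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("Fractional polynomial Cox model: degree %d, powers (%s)\n",
              x$degree, paste(x$powers, collapse = ", ")))
  cat(sprintf("deviance %.2f, reference %g\n", x$deviance, x$reference))
  invisible(x)
}

## FP basis on the analysis scale for a raw-exposure grid
fp_basis_raw <- function(model, grid) {
  fp_transform(grid / model$rescale, model$powers)
}

new_curve_estimate <- function(grid, log_hr, ci_low, ci_high, reference,
                               kind = "observational_fp") {
  out <- data.frame(egfr = grid, log_hr = log_hr,
                    ci_low = ci_low, ci_high = ci_high)
  attr(out, "reference") <- reference
  attr(out, "kind") <- kind
  class(out) <- c("curve_estimate", "data.frame")
  out
}

#' Dose-response curve from a fractional-polynomial model
#'
#' Evaluates `log HR(x) = f(x) - f(reference)` over a grid with pointwise
#' delta-method 95% confidence bounds from the coefficient covariance. The
#' curve is exactly 0 (with zero-width CI) at the reference.
#'
#' @param model An `fp_model`, or a list with elements `coef`, `vcov`,
#'   `powers`, `rescale`, `reference`.
#' @param grid Positive eGFR grid values.
#' @return A `curve_estimate` data frame: `egfr`, `log_hr`, `ci_low`,
#'   `ci_high`; reference stored as an attribute.
#' @export
curve_from_fp <- function(model, grid) {
  assert_that(all(is.finite(grid)) && all(grid > 0),
              "grid values must be positive")
  Bg <- fp_basis_raw(model, grid)
  Br <- fp_basis_raw(model, model$reference)
  D <- sweep(Bg, 2, Br)  # contrast basis against the reference
  est <- drop(D %*% model$coef)
  v <- rowSums((D %*% model$vcov) * D)
  se <- sqrt(pmax(v, 0))
  z <- qnorm(0.975)
  new_curve_estimate(grid, est, est - z * se, est + z * se, model$reference)
}

#' Exclude studies contributing too few events
#'
#' Studies contributing fewer than `threshold` incident events to the
#' analysis of a given outcome are excluded (default threshold 20).
#'
#' @param event_counts Named numeric vector (study -> events) or data frame
#'   with columns `study` and `events`.
#' @param threshold Minimum event count to retain a study.
#' @return Character vector of retained study names.
#' @export
min_events_filter <- function(event_counts, threshold = 20) {
  if (is.data.frame(event_counts)) {
    ec <- setNames(event_counts$events, event_counts$study)
  } else ec <- event_counts
  assert_that(!is.null(names(ec)), "event counts must be named by study")
  keep <- names(ec)[ec >= threshold]
  assert_that(length(keep) > 0,
              "all studies excluded: every study has < %d events", threshold)
  keep
}
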