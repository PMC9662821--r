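## Calibrated multi-study cohort simulator. The generator produces cohorts
## with the statistical structure the downstream analyses assume: a polygenic
## score explaining a controlled share of eGFR variance, a configurable
## piecewise-linear causal log-risk curve anchored at eGFR 90, a confounder
## that raises both eGFR and risk (emulating muscle-mass/hyperfiltration
## artifacts of creatinine-based eGFR), exponential event times with
## administrative censoring, and optional case-cohort subsampling.

#' Simulation scenario configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a three-study consortium of 50,000 participants each with a
#' 218-variant score explaining 2.0/2.2/3.2% of eGFR variance per study, an
#' eGFR distribution centered at 90, a causal log-risk slope of -0.028 per
#' eGFR unit below a changepoint at 75 (0 above), and a confounder raising
#' both eGFR and risk.
#'
#' @param n_per_study Participants per study (>= 100).
#' @param n_studies Number of studies.
#' @param n_variants Number of score variants.
#' @param allele_freqs Optional per-variant effect-allele frequencies in
#'   (0.01, 0.99); generated from the seed if omitted.
#' @param weight_scale Raw per-allele weight scale (eGFR units); relative
#'   magnitudes only, since weights are recalibrated to `target_grs_r2`.
#' @param target_grs_r2 Per-study variance in eGFR explained by the score,
#'   each in (0, 0.2); recycled to `n_studies`.
#' @param egfr_mean,egfr_sd Center and scale (mL/min/1.73m^2) anchoring the
#'   score-variance calibration; per-study total variance is
#'   `var(score)/target_grs_r2`, so studies with smaller targets are
#'   modestly more dispersed.
#' @param causal_curve List with `knots` (increasing changepoints) and
#'   `slopes` (length `length(knots) + 1`), the log-risk slope per eGFR unit
#'   in each interval; the curve value is 0 at the reference (90) and
#'   terminal slopes extrapolate.
#' @param confounder_effect_exposure eGFR units per SD of the confounder.
#' @param confounder_effect_risk Log-hazard per SD of the confounder.
#' @param baseline_hazard Events per person-year at the reference (positive).
#' @param followup_years Administrative censoring time.
#' @param case_cohort_fraction Optional subcohort sampling fraction in (0, 1].
#' @param seed Integer seed (< 2^31).
#' @return Object of class `scenario_config` (validated list).
#' @export
scenario_config <- function(n_per_study = 50000,
                            n_studies = 3,
                            n_variants = 218,
                            allele_freqs = NULL,
                            weight_scale = 0.15,
                            target_grs_r2 = c(0.020, 0.022, 0.032),
                            egfr_mean = 90,
                            egfr_sd = 19,
                            causal_curve = list(knots = 75,
                                                slopes = c(-0.028, 0)),
                            confounder_effect_exposure = 6,
                            confounder_effect_risk = 0.3,
                            baseline_hazard = 0.01,
                            followup_years = 15,
                            case_cohort_fraction = NULL,
                            seed = 1L) {
  cfg <- list(n_per_study = n_per_study, n_studies = n_studies,
              n_variants = n_variants, allele_freqs = allele_freqs,
              weight_scale = weight_scale,
              target_grs_r2 = rep_len(target_grs_r2, n_studies),
              egfr_mean = egfr_mean, egfr_sd = egfr_sd,
              causal_curve = causal_curve,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_risk = confounder_effect_risk,
              baseline_hazard = baseline_hazard,
              followup_years = followup_years,
              case_cohort_fraction = case_cohort_fraction,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  assert_that(cfg$n_per_study >= 100, "n_per_study must be >= 100")
  assert_that(cfg$n_studies >= 1, "n_studies must be >= 1")
  assert_that(cfg$n_variants >= 1, "n_variants must be >= 1")
  if (!is.null(cfg$allele_freqs))
    check_range(cfg$allele_freqs, 0.01, 0.99, "allele_freqs",
                open_lo = TRUE, open_hi = TRUE)
  check_range(cfg$target_grs_r2, 0, 0.2, "target_grs_r2",
              open_lo = TRUE, open_hi = TRUE)
  assert_that(is.list(cfg$causal_curve) &&
                all(c("knots", "slopes") %in% names(cfg$causal_curve)),
              "causal_curve must be a list with 'knots' and 'slopes'")
  kn <- cfg$causal_curve$knots
  assert_that(length(cfg$causal_curve$slopes) == length(kn) + 1,
              "causal_curve needs length(knots) + 1 slopes")
  assert_that(length(kn) == 0 || all(diff(kn) > 0),
              "causal_curve knots must be strictly increasing")
  assert_that(is.finite(cfg$baseline_hazard) && cfg$baseline_hazard >= 0,
              "baseline_hazard must be non-negative")
  assert_that(cfg$followup_years >= 0, "followup_years must be non-negative")
  if (!is.null(cfg$case_cohort_fraction))
    check_range(cfg$case_cohort_fraction, 0, 1, "case_cohort_fraction",
                open_lo = TRUE)
  assert_that(abs(cfg$seed) < 2^31, "seed must fit a 32-bit integer")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %d studies x %d participants, %d variants\n",
              x$n_studies, x$n_per_study, x$n_variants))
  cat(sprintf("  target score R^2: %s\n",
              paste(format(x$target_grs_r2), collapse = ", ")))
  cat(sprintf("  eGFR ~ %g (sd anchor %g); causal slopes (%s) at knots (%s)\n",
              x$egfr_mean, x$egfr_sd,
              paste(x$causal_curve$slopes, collapse = ", "),
              paste(x$causal_curve$knots, collapse = ", ")))
  invisible(x)
}

#' Causal log-risk at a given eGFR
#'
#' Evaluates the configured piecewise-linear causal curve (log hazard
#' relative to the reference, which is 0 at the reference by construction).
#'
#' @param egfr Numeric eGFR values.
#' @param curve List with `knots` and `slopes` (see [scenario_config()]).
#' @param reference Anchoring point, default 90.
#' @return Numeric log-risk values.
#' @export
causal_log_risk <- function(egfr, curve, reference = 90) {
  ## finite hull keeps the cumulative-integral evaluation well conditioned
  lo <- min(egfr, reference, curve$knots) - 1
  hi <- max(egfr, reference, curve$knots) + 1
  piecewise_value(egfr, c(lo, curve$knots, hi), curve$slopes, reference)
}

#' Simulate independent genotype dosages
#'
#' Dosages 0/1/2 drawn binomially per variant under Hardy-Weinberg
#' proportions, independent across variants (no linkage disequilibrium: the
#' score, not the individual variants, is the instrument downstream).
#'
#' @param n Number of participants.
#' @param allele_freqs Effect-allele frequencies in (0.01, 0.99).
#' @param seed Integer seed.
#' @return Integer matrix n x J with variant ids `v001...` as column names
#'   and a `coded_allele` attribute (the effect allele of each variant).
#' @export
simulate_genotypes <- function(n, allele_freqs, seed) {
  check_range(allele_freqs, 0.01, 0.99, "allele_freqs",
              open_lo = TRUE, open_hi = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  J <- length(allele_freqs)
  g <- matrix(0L, n, J)
  for (j in seq_len(J)) g[, j] <- rbinom(n, 2L, allele_freqs[j])
  colnames(g) <- sprintf("v%03d", seq_len(J))
  ## allele labels are a property of the variant, not of the draw: keep them
  ## deterministic so matrices simulated per study stay orientation-consistent
  alleles <- c("A", "C", "G", "T")[(seq_len(J) - 1L) %% 4L + 1L]
  attr(g, "coded_allele") <- setNames(alleles, colnames(g))
  attr(g, "allele_freqs") <- setNames(allele_freqs, colnames(g))
  g
}

#' Variant weights calibrated to a target score variance
#'
#' Draws raw per-allele weights and rescales them so the population variance
#' of the score, `sum w^2 2p(1-p)`, equals
#' `mean(target_grs_r2) * egfr_sd^2`. Exclusion flags are all FALSE.
#'
#' @param config A `scenario_config`.
#' @param genotypes Genotype matrix from [simulate_genotypes()] (supplies
#'   variant ids, alleles and frequencies).
#' @return Data frame: `variant_id`, `effect_allele`, `weight` (eGFR units
#'   per effect allele), `flag_ancestry`, `flag_riskfactor`, `flag_missing`.
#' @export
make_variant_weights <- function(config, genotypes) {
  freqs <- attr(genotypes, "allele_freqs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 997))
  w_raw <- rnorm(ncol(genotypes), 0, config$weight_scale)
  v_raw <- sum(w_raw^2 * 2 * freqs * (1 - freqs))
  v_target <- mean(config$target_grs_r2) * config$egfr_sd^2
  w <- w_raw * sqrt(v_target / v_raw)
  data.frame(variant_id = colnames(genotypes),
             effect_allele = unname(attr(genotypes, "coded_allele")),
             weight = w,
             flag_ancestry = FALSE, flag_riskfactor = FALSE,
             flag_missing = FALSE)
}

#' Simulate eGFR, confounder and covariates for one study
#'
#' Generates `eGFR = egfr_mean + (score - E[score]) + b_U * U + e` with `U`
#' standard normal and the Gaussian noise variance solved analytically so
#' that the score explains `target_r2` of the population exposure variance
#' (`var(exposure) = var(score)/target_r2`). Also generates demographics and
#' risk-factor covariates (age, sex, center, SBP, cholesterol, HDL, BMI,
#' smoking, 10 principal components), none of which enter the exposure or
#' event models; they exercise the adjustment machinery downstream.
#'
#' @param genotypes Genotype matrix.
#' @param weights Calibrated weight table (see [make_variant_weights()]).
#' @param config A `scenario_config`.
#' @param target_r2 Target score R^2 for this study (default: first entry).
#' @param seed Integer seed (default derived from the config seed).
#' @return Data frame with `id`, `age`, `sex`, `center`, `egfr`,
#'   `confounder`, `score_true`, risk factors and `pc1..pc10`.
#' @export
simulate_exposure <- function(genotypes, weights, config,
                              target_r2 = config$target_grs_r2[1],
                              seed = derive_seed(config$seed, 1)) {
  assert_that(all(weights$variant_id %in% colnames(genotypes)),
              "weight and genotype variant sets do not match")
  check_range(target_r2, 0, 0.2, "target_r2", open_lo = TRUE, open_hi = TRUE)
  n <- nrow(genotypes)
  freqs <- attr(genotypes, "allele_freqs")[weights$variant_id]
  v_g <- sum(weights$weight^2 * 2 * freqs * (1 - freqs))
  mu_g <- sum(weights$weight * 2 * freqs)
  v_x <- if (v_g > 0) v_g / target_r2 else config$egfr_sd^2
  v_noise <- v_x - v_g - config$confounder_effect_exposure^2
  assert_that(v_noise > 0,
              paste("infeasible variance decomposition: target_r2 and the",
                    "confounder share exceed the total exposure variance"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  score <- compute_grs(genotypes, weights)
  U <- rnorm(n)
  egfr <- config$egfr_mean + (score - mu_g) +
    config$confounder_effect_exposure * U + rnorm(n, 0, sqrt(v_noise))
  egfr <- pmax(egfr, 2)  # physiological floor; affects a vanishing tail
  age <- rnorm(n, 57, 8)
  sex <- ifelse(runif(n) < 0.57, "male", "female")
  data.frame(
    id = seq_len(n),
    age = age, sex = sex,
    center = paste0("C", sample.int(4, n, replace = TRUE)),
    egfr = egfr, confounder = U, score_true = score,
    sbp = rnorm(n, 135, 18), tchol = rnorm(n, 5.6, 1.1),
    hdl = pmax(rnorm(n, 1.4, 0.4), 0.3), bmi = pmax(rnorm(n, 27, 4.5), 14),
    smoking = ifelse(runif(n) < 0.22, "current", "other"),
    history_cvd = runif(n) < 0.03, history_diabetes = runif(n) < 0.05,
    matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("pc", 1:10))))
}

#' Simulate right-censored event times
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(causal_log_risk(egfr) + confounder_effect_risk * U)`
#' and administratively censored at `followup_years`. The causal
#' contribution uses the configured piecewise-linear curve anchored at the
#' reference (value 0 at eGFR 90).
#'
#' @param exposure_tab Data frame with `egfr` and `confounder` columns.
#' @param config A `scenario_config`.
#' @param seed Integer seed.
#' @return `exposure_tab` with added `event` (0/1) and `time` (years).
#' @export
simulate_events <- function(exposure_tab, config,
                            seed = derive_seed(config$seed, 2)) {
  assert_that(config$baseline_hazard >= 0, "baseline_hazard must be non-negative")
  n <- nrow(exposure_tab)
  rate <- config$baseline_hazard *
    exp(causal_log_risk(exposure_tab$egfr, config$causal_curve) +
          config$confounder_effect_risk * exposure_tab$confounder)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t_event <- if (config$baseline_hazard == 0) rep(Inf, n) else rexp(n, rate)
  exposure_tab$event <- as.integer(t_event <= config$followup_years)
  exposure_tab$time <- pmin(t_event, config$followup_years)
  exposure_tab
}

#' Apply a case-cohort design
#'
#' Flags a random subcohort of expected size `fraction * n`; all cases are
#' retained (with their case status); non-subcohort non-cases are dropped
#' from the analysis view. With `fraction = 1` the design is the full
#' cohort.
#'
#' @param cohort A `simulated_cohort` (see [simulate_cohort()]).
#' @param fraction Subcohort sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return The cohort with `participants$subcohort` set and non-subcohort
#'   non-cases removed from `participants` and `genotypes`.
#' @export
apply_case_cohort <- function(cohort, fraction, seed) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  check_range(fraction, 0, 1, "fraction", open_lo = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(cohort$participants)
  sub <- runif(n) < fraction
  keep <- sub | cohort$participants$event == 1
  cohort$participants$subcohort <- sub
  cohort$participants <- cohort$participants[keep, , drop = FALSE]
  ca <- attr(cohort$genotypes, "coded_allele")
  af <- attr(cohort$genotypes, "allele_freqs")
  cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  attr(cohort$genotypes, "coded_allele") <- ca
  attr(cohort$genotypes, "allele_freqs") <- af
  cohort$truth$case_cohort_fraction <- fraction
  cohort
}

#' Simulate a multi-study cohort
#'
#' Runs the full generator: shared variant weights calibrated to the
#' per-study variance-explained targets, then per study genotypes, exposure,
#' covariates and right-censored events. Study 1 is marked as not
#' IDMS-standardized (its written creatinine is the calibrated value divided
#' by 0.95, so the calibration step downstream reproduces the simulated
#' eGFR); other studies are standardized. Creatinine is obtained by
#' inverting the 2009 CKD-EPI equation at the simulated eGFR.
#'
#' @param config A `scenario_config`.
#' @return Object of class `simulated_cohort`: list with `participants`
#'   (one row per participant across studies), `genotypes` (row-aligned
#'   dosage matrix), `weights`, and `truth` (config echo plus realized
#'   per-study score R^2).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  freqs <- config$allele_freqs
  if (is.null(freqs)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, 499))
    freqs <- runif(config$n_variants, 0.05, 0.95)
    .Random.seed_restore(old)
  }
  parts <- vector("list", config$n_studies)
  genos <- vector("list", config$n_studies)
  weights <- NULL
  realized_r2 <- numeric(config$n_studies)
  for (s in seq_len(config$n_studies)) {
    g <- simulate_genotypes(config$n_per_study, freqs,
                            seed = derive_seed(config$seed, 10 * s))
    if (is.null(weights)) weights <- make_variant_weights(config, g)
    tab <- simulate_exposure(g, weights, config,
                             target_r2 = config$target_grs_r2[s],
                             seed = derive_seed(config$seed, 10 * s + 1))
    tab <- simulate_events(tab, config,
                           seed = derive_seed(config$seed, 10 * s + 2))
    study_id <- paste0("S", s)
    tab$study <- study_id
    tab$id <- sprintf("%s_%06d", study_id, seq_len(nrow(tab)))
    tab$center <- paste0(study_id, "_", tab$center)
    tab$idms_standardized <- s != 1
    creat <- ckd_epi_2009_invert(tab$egfr, tab$sex, tab$age)
    tab$creatinine <- ifelse(tab$idms_standardized, creat, creat / 0.95)
    tab$subcohort <- TRUE
    realized_r2[s] <- cor(tab$score_true, tab$egfr)^2
    rownames(g) <- tab$id
    parts[[s]] <- tab
    genos[[s]] <- g
  }
  participants <- do.call(rbind, parts)
  genotypes <- do.call(rbind, genos)
  attr(genotypes, "coded_allele") <- attr(genos[[1]], "coded_allele")
  attr(genotypes, "allele_freqs") <- attr(genos[[1]], "allele_freqs")
  rownames(participants) <- NULL
  out <- list(participants = participants, genotypes = genotypes,
              weights = weights,
              truth = list(config = config,
                           realized_r2 = setNames(realized_r2,
                                                  paste0("S", seq_len(config$n_studies)))))
  class(out) <- "simulated_cohort"
  if (!is.null(config$case_cohort_fraction) &&
      config$case_cohort_fraction < 1) {
    out <- apply_case_cohort(out, config$case_cohort_fraction,
                             seed = derive_seed(config$seed, 3))
  }
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated cohort: %d participants in %d studies, %d variants\n",
              nrow(x$participants), cfg$n_studies, ncol(x$genotypes)))
  cat(sprintf("  events: %d (%.1f%%); realized score R^2: %s\n",
              sum(x$participants$event),
              100 * mean(x$participants$event),
              paste(sprintf("%.3f", x$truth$realized_r2), collapse = ", ")))
  invisible(x)
}
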