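## File formats, run configuration and end-to-end orchestration.
## All tables are plain TSV; run metadata is JSON; configuration is YAML.

#' @importFrom data.table fread fwrite as.data.table
NULL

#' Write a simulated cohort to TSV files
#'
#' Emits the phenotype table (`phenotype.tsv`), the genotype dosage matrix
#' (`genotypes.tsv`, id x variant), the variant weight table
#' (`weights.tsv`) and the scenario configuration (`scenario.yaml`).
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(phenotype = file.path(dir, "phenotype.tsv"),
                genotypes = file.path(dir, "genotypes.tsv"),
                weights = file.path(dir, "weights.tsv"),
                scenario = file.path(dir, "scenario.yaml"))
  fwrite(cohort$participants, paths$phenotype, sep = "\t")
  g <- as.data.table(cohort$genotypes)
  g <- cbind(data.table::data.table(id = cohort$participants$id), g)
  fwrite(g, paths$genotypes, sep = "\t")
  fwrite(cohort$weights, paths$weights, sep = "\t")
  cfg <- cohort$truth$config
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, paths$scenario)
  invisible(paths)
}

#' Load and validate the analysis tables
#'
#' Reads the phenotype, genotype-dosage and variant-weight TSVs, validates
#' schemas, applies unit handling, verifies the id join between phenotype
#' and genotype tables and reports orphans.
#'
#' Validation rules: phenotype rows with non-positive creatinine are
#' rejected (tallied); duplicate participant or variant ids are errors;
#' genotype rows that do not join the phenotype table are reported as
#' orphans and dropped; weight files without flag columns default all flags
#' to FALSE with a warning. Genotype dosages are taken to be coded on the
#' weight table's effect allele.
#'
#' @param paths Named list/vector with `phenotype`, `genotypes`, `weights`.
#' @param creatinine_unit `"mg/dl"` (default) or `"umol/l"` (converted).
#' @return List: `records` (data frame), `genotypes` (numeric matrix with
#'   `coded_allele` attribute), `weights`, `issues` (list of tallies and
#'   orphan ids).
#' @export
load_tables <- function(paths, creatinine_unit = c("mg/dl", "umol/l")) {
  creatinine_unit <- match.arg(creatinine_unit)
  for (p in c("phenotype", "genotypes", "weights"))
    assert_that(!is.null(paths[[p]]) && file.exists(paths[[p]]),
                "missing input file for '%s'", p)
  rec <- as.data.frame(fread(paths$phenotype, sep = "\t"))
  need <- c("id", "study", "sex", "age", "creatinine", "event", "time")
  assert_that(all(need %in% names(rec)), "phenotype table lacks columns: %s",
              paste(setdiff(need, names(rec)), collapse = ", "))
  assert_that(!anyDuplicated(rec$id), "duplicate participant ids")
  issues <- list()
  bad_creat <- !is.na(rec$creatinine) & rec$creatinine <= 0
  issues$rejected_nonpositive_creatinine <- sum(bad_creat)
  rec <- rec[!bad_creat, , drop = FALSE]
  if (creatinine_unit == "umol/l")
    rec$creatinine <- creatinine_umol_to_mgdl(rec$creatinine)

  wt <- as.data.frame(fread(paths$weights, sep = "\t"))
  assert_that(all(c("variant_id", "weight") %in% names(wt)),
              "weights table needs 'variant_id' and 'weight'")
  flag_cols <- c("flag_ancestry", "flag_riskfactor", "flag_missing")
  if (!all(flag_cols %in% names(wt))) {
    warning("weights file lacks flag columns; defaulting all flags to FALSE")
    for (fc in setdiff(flag_cols, names(wt))) wt[[fc]] <- FALSE
  }
  assert_that(!anyDuplicated(wt$variant_id), "duplicate variant ids in weights")

  gt <- fread(paths$genotypes, sep = "\t")
  assert_that("id" %in% names(gt), "genotype table needs an 'id' column")
  ids <- as.character(gt$id)
  assert_that(!anyDuplicated(ids), "duplicate ids in genotype table")
  orphans <- setdiff(ids, as.character(rec$id))
  issues$orphan_genotype_ids <- orphans
  g <- as.matrix(gt[, -1, drop = FALSE])
  rownames(g) <- ids
  g <- g[ids %in% as.character(rec$id), , drop = FALSE]
  ## align phenotype rows to genotype rows where both exist
  if ("effect_allele" %in% names(wt)) {
    ca <- setNames(as.character(wt$effect_allele), wt$variant_id)
    attr(g, "coded_allele") <- ca[colnames(g)]
    names(attr(g, "coded_allele")) <- colnames(g)
  }
  list(records = rec, genotypes = g, weights = wt, issues = issues)
}

#' Run configuration for the analysis pipeline
#'
#' @param paths Named list with `phenotype`, `genotypes`, `weights` paths.
#' @param arm `"both"`, `"observational"` or `"mr"`.
#' @param stratification `"residual"` or `"doubly_ranked"`.
#' @param n_strata Strata for the doubly-ranked method (default 10).
#' @param covariates_obs Adjustment terms for the observational arm.
#' @param covariates_mr Adjustment terms for the MR stratum regressions.
#' @param B Resampling draws for the MR curve CI.
#' @param seed Integer seed.
#' @param min_events Per-study minimum event count (default 20).
#' @param min_stratum_n,min_stratum_events Stratum floors for LACE.
#' @param include_diabetes Sensitivity switch: retain participants with a
#'   history of diabetes.
#' @param out_dir Optional output directory; if given, tables and metadata
#'   are written there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(paths,
                       arm = c("both", "observational", "mr"),
                       stratification = c("residual", "doubly_ranked"),
                       n_strata = 10,
                       covariates_obs = c("age", "sbp", "tchol", "hdl",
                                          "bmi", "smoking"),
                       covariates_mr = c("age", "I(age^2)", "sex", "center",
                                         paste0("pc", 1:10)),
                       B = 1000, seed = 1L, min_events = 20,
                       min_stratum_n = 100, min_stratum_events = 10,
                       include_diabetes = FALSE, out_dir = NULL) {
  arm <- match.arg(arm)
  stratification <- match.arg(stratification)
  assert_that(min_events > 0 && min_stratum_n > 0 && min_stratum_events > 0,
              "thresholds must be positive")
  cfg <- list(paths = paths, arm = arm, stratification = stratification,
              n_strata = n_strata, covariates_obs = covariates_obs,
              covariates_mr = covariates_mr, B = B, seed = as.integer(seed),
              min_events = min_events, min_stratum_n = min_stratum_n,
              min_stratum_events = min_stratum_events,
              include_diabetes = include_diabetes, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Sequences: load tables -> creatinine calibration and eGFR computation ->
#' eligibility filtering -> genetic risk score (variant exclusions, score,
#' variance explained) -> the chosen analysis arm(s) -> meta-analytic
#' pooling -> outputs. All outputs carry the configuration hash and seeds;
#' the run log records exclusion tallies and per-study event counts.
#'
#' @param config A `run_config` (or path to its YAML).
#' @return Report bundle (class `pipeline_report`): list with `grs`,
#'   `observational`, `mr`, `eligibility`, `event_counts`, `meta`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  meta <- list(seed = config$seed,
               config_hash = config_hash(jsonlite::toJSON(
                 config[setdiff(names(config), "out_dir")],
                 auto_unbox = TRUE, force = TRUE)),
               B = config$B,
               stratification = config$stratification,
               floors = list(min_events = config$min_events,
                             min_stratum_n = config$min_stratum_n,
                             min_stratum_events = config$min_stratum_events))

  inputs <- pipeline_stage("load", load_tables(config$paths))
  rec <- inputs$records

  rec <- pipeline_stage("kidney_metrics", {
    if (!"idms_standardized" %in% names(rec)) rec$idms_standardized <- TRUE
    rec$creatinine <- idms_calibrate(rec$creatinine,
                                     as.logical(rec$idms_standardized))
    rec$egfr <- ckd_epi_2009(rec$creatinine, rec$sex, rec$age)
    rec
  })

  elig <- pipeline_stage("eligibility", {
    r <- rec
    if (config$include_diabetes) r$history_diabetes <- FALSE
    eligibility_filter(r)
  })
  rec <- elig$records

  grs_out <- pipeline_stage("grs", {
    filt <- filter_variants(inputs$weights)
    g <- inputs$genotypes[match(as.character(rec$id),
                                rownames(inputs$genotypes)), , drop = FALSE]
    assert_that(!anyNA(g[, 1]), "phenotype ids missing from genotype table")
    attr(g, "coded_allele") <- attr(inputs$genotypes, "coded_allele")
    score <- compute_grs(g, filt$retained)
    rec$score <- score
    ## standardize per study against the analysis sample SD
    rec$score_std <- stats::ave(score, rec$study,
                                FUN = function(z) (z - mean(z)) / sd(z))
    per_study <- lapply(split(rec, rec$study), function(d)
      variance_explained(d$score, d$egfr))
    list(filter = filt, records = rec,
         r2 = vapply(per_study, `[[`, 0, "r2"),
         sd_slope = vapply(per_study, `[[`, 0, "sd_slope"))
  })
  rec <- grs_out$records

  event_counts <- vapply(split(rec$event, rec$study), sum, 0)

  obs <- NULL
  if (config$arm %in% c("both", "observational")) {
    obs <- pipeline_stage("observational", {
      keep <- min_events_filter(event_counts, config$min_events)
      d <- rec[rec$study %in% keep, , drop = FALSE]
      ## power selection on the combined data, study centers as strata
      sel <- fit_fractional_polynomial(d, exposure = "egfr",
                                       covariates = config$covariates_obs,
                                       strata_cols = c("sex", "center"))
      studies <- unique(d$study)
      fits <- lapply(studies, function(s)
        fit_fractional_polynomial(d[d$study == s, , drop = FALSE],
                                  exposure = "egfr",
                                  covariates = config$covariates_obs,
                                  strata_cols = c("sex", "center"),
                                  powers = sel$powers))
      pooled_model <- if (length(fits) >= 2) {
        mv <- multivariate_random_effects(lapply(fits, `[[`, "coef"),
                                          lapply(fits, `[[`, "vcov"))
        list(coef = setNames(mv$estimate, names(fits[[1]]$coef)),
             vcov = mv$vcov, powers = sel$powers, rescale = sel$rescale,
             reference = sel$reference, mv = mv)
      } else fits[[1]]
      lo <- max(quantile(d$egfr, 0.005), 30)
      hi <- min(quantile(d$egfr, 0.995), 150)
      curve <- curve_from_fp(pooled_model, sort(unique(c(
        seq(ceiling(lo), floor(hi)), sel$reference))))
      list(selected_powers = sel$powers, selection = sel$selection,
           study_fits = setNames(fits, studies), pooled_model = pooled_model,
           curve = curve, studies_retained = keep)
    })
  }

  mr <- NULL
  if (config$arm %in% c("both", "mr")) {
    mr <- pipeline_stage("mr", {
      per_study <- lapply(split(rec, rec$study), function(d) {
        if (config$stratification == "residual") {
          d <- residual_stratify(d, score_col = "score_std",
                                 exposure_col = "egfr")
        } else {
          d$stratum <- factor(doubly_ranked_stratify(d$score_std, d$egfr,
                                                     config$n_strata),
                              levels = seq_len(config$n_strata))
        }
        stratum_estimates(d, score_col = "score_std",
                          exposure_col = "egfr", outcome_col = "event",
                          covariates = config$covariates_mr,
                          min_n = config$min_stratum_n,
                          min_events = config$min_stratum_events)
      })
      est <- do.call(rbind, Map(function(e, s) {
        if (nrow(e)) e$study <- s
        e
      }, per_study, names(per_study)))
      pooled <- pool_strata(est)
      curve <- build_piecewise_curve(pooled, reference = 90, B = config$B,
                                     seed = derive_seed(config$seed, 77))
      trend <- if (nrow(pooled) >= 3) lace_trend_tests(pooled) else NULL
      list(per_study = est, pooled = pooled, curve = curve, trend = trend)
    })
  }

  report <- list(grs = grs_out[c("filter", "r2", "sd_slope")],
                 eligibility = elig[c("tally", "n_input", "n_retained")],
                 event_counts = event_counts,
                 observational = obs, mr = mr, meta = meta,
                 issues = inputs$issues)
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the report bundle to disk
#'
#' Emits the pooled and per-study stratum-estimate TSV, the observational
#' and MR curve TSVs, and a JSON metadata file (config hash, seeds, floors,
#' eligibility tallies, per-study event counts).
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(report$mr)) {
    p <- file.path(dir, "stratum_estimates.tsv")
    fwrite(report$mr$per_study, p, sep = "\t"); paths <- c(paths, p)
    p <- file.path(dir, "stratum_pooled.tsv")
    fwrite(report$mr$pooled, p, sep = "\t"); paths <- c(paths, p)
    p <- file.path(dir, "mr_curve.tsv")
    fwrite(as.data.frame(report$mr$curve), p, sep = "\t")
    paths <- c(paths, p)
  }
  if (!is.null(report$observational)) {
    p <- file.path(dir, "observational_curve.tsv")
    fwrite(as.data.frame(report$observational$curve), p, sep = "\t")
    paths <- c(paths, p)
    p <- file.path(dir, "fp_model.json")
    pm <- report$observational$pooled_model
    jsonlite::write_json(list(powers = pm$powers, coef = as.list(pm$coef),
                              vcov = pm$vcov, rescale = pm$rescale,
                              reference = pm$reference),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(list(meta = report$meta,
                            eligibility = report$eligibility,
                            event_counts = as.list(report$event_counts),
                            grs_r2 = as.list(report$grs$r2),
                            variant_filter = report$grs$filter[
                              c("n_input", "n_retained", "flag_counts")]),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  eligibility: %d of %d retained\n",
              x$eligibility$n_retained, x$eligibility$n_input))
  cat(sprintf("  variants: %d of %d retained\n",
              x$grs$filter$n_retained, x$grs$filter$n_input))
  cat(sprintf("  score R^2 by study: %s\n",
              paste(sprintf("%s=%.3f", names(x$grs$r2), x$grs$r2),
                    collapse = ", ")))
  if (!is.null(x$mr))
    cat(sprintf("  MR: %d pooled strata; curve anchored at %g\n",
                nrow(x$mr$pooled), attr(x$mr$curve, "reference")))
  if (!is.null(x$observational))
    cat(sprintf("  observational: FP powers (%s)\n",
                paste(x$observational$selected_powers, collapse = ", ")))
  invisible(x)
}

#' Plot a dose-response curve
#'
#' Base-graphics plot of a `curve_estimate` (observational or MR) with its
#' pointwise 95% band and the reference point marked.
#'
#' @param x A `curve_estimate`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.curve_estimate <- function(x, ...) {
  graphics::plot(x$egfr, x$log_hr, type = "l",
                 xlab = "eGFR (mL/min/1.73m^2)",
                 ylab = "log relative risk", ...)
  graphics::polygon(c(x$egfr, rev(x$egfr)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(x$egfr, x$log_hr, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::points(attr(x, "reference"), 0, pch = 19)
  invisible(x)
}
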