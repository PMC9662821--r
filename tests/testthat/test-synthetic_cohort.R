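test_that("scenario config validates its invariants", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_per_study = 50), "n_per_study")
  expect_error(scenario_config(target_grs_r2 = 0.5), "target_grs_r2")
  expect_error(scenario_config(allele_freqs = c(0.5, 1.2)), "allele_freqs")
  expect_error(scenario_config(causal_curve = list(knots = c(80, 75),
                                                   slopes = c(0, 0, 0))),
               "increasing")
  expect_error(scenario_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(scenario_config(case_cohort_fraction = 0), "case_cohort")
})

test_that("genotypes are binomial dosages with the requested frequencies", {
  g <- simulate_genotypes(1e5, 0.5, seed = 1)
  expect_true(all(g %in% 0:2))
  expect_gt(mean(g), 0.99); expect_lt(mean(g), 1.01)

  g2 <- simulate_genotypes(10, c(0.011, 0.5), seed = 2)
  expect_true(all(g2 %in% 0:2))

  expect_identical(simulate_genotypes(50, c(0.2, 0.7), seed = 3),
                   simulate_genotypes(50, c(0.2, 0.7), seed = 3))
  expect_error(simulate_genotypes(10, 0.005, seed = 1), "allele_freqs")
  expect_error(simulate_genotypes(10, NaN, seed = 1), "finite")
})

test_that("per-variant sample frequencies approach the target as n grows", {
  freqs <- c(0.1, 0.3, 0.8)
  g <- simulate_genotypes(2e5, freqs, seed = 4)
  expect_equal(colMeans(g) / 2, freqs, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("exposure simulation hits the target variance explained", {
  cfg <- scenario_config(n_per_study = 1e5, n_variants = 16, seed = 5)
  g <- simulate_genotypes(1e5, runif(16, 0.1, 0.9), seed = 6)
  w <- make_variant_weights(cfg, g)
  tab <- simulate_exposure(g, w, cfg, target_r2 = 0.032, seed = 7)
  r2 <- cor(tab$score_true, tab$egfr)^2
  expect_lt(abs(r2 - 0.032), 0.004)
  ## independent brute-force check: regression R^2 equals squared correlation
  expect_equal(summary(lm(egfr ~ score_true, tab))$r.squared, r2,
               tolerance = 1e-10)
})

test_that("null weights give a score explaining nothing", {
  cfg <- scenario_config(n_per_study = 5000, n_variants = 8, seed = 8,
                         weight_scale = 0.15)
  g <- simulate_genotypes(5000, runif(8, 0.2, 0.8), seed = 9)
  w <- make_variant_weights(cfg, g)
  w$weight <- 0
  tab <- simulate_exposure(g, w, cfg, target_r2 = 0.03, seed = 10)
  expect_equal(var(tab$score_true), 0)
  ## exposure variance then equals the confounder + noise share (anchor sd)
  expect_equal(sd(tab$egfr), cfg$egfr_sd, tolerance = 0.03)
})

test_that("infeasible variance decompositions are rejected", {
  cfg <- scenario_config(n_per_study = 1000, n_variants = 4, seed = 11,
                         confounder_effect_exposure = 19)
  g <- simulate_genotypes(1000, rep(0.5, 4), seed = 12)
  w <- make_variant_weights(cfg, g)
  ## confounder SD (19) ~ the whole anchor SD: nothing left for noise
  expect_error(simulate_exposure(g, w, cfg, target_r2 = 0.15),
               "infeasible")
})

test_that("calibration: mean realized R2 over replicates is within 0.004", {
  cfg <- scenario_config(n_per_study = 1e5, n_variants = 12, seed = 13)
  freqs <- runif(12, 0.1, 0.9)
  r2 <- vapply(1:50, function(r) {
    g <- simulate_genotypes(1e5, freqs, seed = 1000 + r)
    w <- make_variant_weights(cfg, g)
    tab <- simulate_exposure(g, w, cfg, target_r2 = 0.022, seed = 2000 + r)
    cor(tab$score_true, tab$egfr)^2
  }, 0)
  expect_lt(abs(mean(r2) - 0.022), 0.004)
})

test_that("event times follow the configured exponential model", {
  ## zero slopes and no confounder effect: closed-form event rate
  cfg <- scenario_config(n_per_study = 2e5, n_variants = 4, seed = 14,
                         causal_curve = list(knots = numeric(0), slopes = 0),
                         confounder_effect_risk = 0)
  g <- simulate_genotypes(2e5, rep(0.5, 4), seed = 15)
  w <- make_variant_weights(cfg, g)
  tab <- simulate_exposure(g, w, cfg, target_r2 = 0.02, seed = 16)
  tab <- simulate_events(tab, cfg, seed = 17)
  expected <- 1 - exp(-cfg$baseline_hazard * cfg$followup_years)
  expect_equal(mean(tab$event), expected, tolerance = 0.01)
})

test_that("the causal curve is piecewise linear with extrapolated tails", {
  curve <- list(knots = 75, slopes = c(-0.028, 0))
  expect_equal(causal_log_risk(75, curve), 0)   # flat from 75 to 90
  expect_equal(causal_log_risk(90, curve), 0)
  expect_equal(causal_log_risk(120, curve), 0)
  ## hazard ratio at 70 vs 75 is exp(0.14)
  h70 <- exp(causal_log_risk(70, curve)); h75 <- exp(causal_log_risk(75, curve))
  expect_equal(h70 / h75, exp(0.14), tolerance = 1e-12)
  expect_equal(causal_log_risk(40, curve), 0.028 * 35, tolerance = 1e-12)
})

test_that("zero follow-up plus the one-year rule leaves no usable events", {
  cfg <- scenario_config(n_per_study = 300, n_variants = 4, seed = 18,
                         followup_years = 0)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$participants$event), 0)
  el <- eligibility_filter(co$participants)
  expect_equal(el$n_retained, 0)  # everyone fails the >= 1 year criterion
})

test_that("case-cohort designs keep all cases and a binomial subcohort", {
  cfg <- scenario_config(n_per_study = 10000, n_studies = 1, n_variants = 6,
                         seed = 19)
  co <- simulate_cohort(cfg)
  n <- nrow(co$participants)
  cc <- apply_case_cohort(co, 0.1, seed = 20)
  expect_true(all(co$participants$id[co$participants$event == 1] %in%
                    cc$participants$id))
  n_sub <- sum(cc$participants$subcohort)
  ## binomial 99% bounds around 0.1 * n
  expect_true(abs(n_sub - 0.1 * n) < 2.58 * sqrt(n * 0.1 * 0.9))
  expect_true(all(cc$participants$subcohort | cc$participants$event == 1))
  ## determinism and the identity design
  cc2 <- apply_case_cohort(co, 0.1, seed = 20)
  expect_identical(cc$participants$id, cc2$participants$id)
  full <- apply_case_cohort(co, 1, seed = 21)
  expect_equal(nrow(full$participants), n)
  expect_error(apply_case_cohort(co, 0, seed = 1), "fraction")
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- small_scenario(n_per_study = 500, seed = 22)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$weights, c2$weights)
})

test_that("genotype and participant row counts match and events occur", {
  cfg <- small_scenario(n_per_study = 800, seed = 23)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$participants), nrow(co$genotypes))
  expect_gt(mean(co$participants$event), 0)
  ## written creatinine reproduces the simulated eGFR through the
  ## calibration + CKD-EPI path
  creat <- idms_calibrate(co$participants$creatinine,
                          co$participants$idms_standardized)
  egfr <- ckd_epi_2009(creat, co$participants$sex, co$participants$age)
  expect_equal(egfr, co$participants$egfr, tolerance = 1e-8)
})

test_that("the confounder induces an observational U-shape that MR does not show", {
  ## one large cohort: the creatinine-artifact confounder raises both eGFR
  ## and risk, so the observational curve turns upward above the reference
  ## while the causal (MR) curve stays flat there
  cfg <- scenario_config(n_per_study = 25000, n_studies = 2, n_variants = 16,
                         seed = 77)
  co <- simulate_cohort(cfg)
  rec <- eligibility_filter(co$participants)$records
  co$participants <- rec
  co$genotypes <- co$genotypes[match(rec$id, rownames(co$genotypes)), ,
                               drop = FALSE]
  fp <- fit_fractional_polynomial(rec, covariates = c("age", "sbp", "tchol",
                                                      "hdl", "bmi", "smoking"))
  cv <- curve_from_fp(fp, c(60, 90, 110))
  expect_gt(cv$log_hr[cv$egfr == 110], 0)     # exceeds the value at 90 (= 0)
  expect_gt(cv$log_hr[cv$egfr == 60], 0)      # and risk is elevated below 75

  ch <- mr_chain(co)
  pl <- pool_strata(ch$per_study)
  high <- pl[as.character(pl$stratum) == ">=105", ]
  expect_true(high$lace - 1.96 * high$se <= 0 &
                0 <= high$lace + 1.96 * high$se)
})
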