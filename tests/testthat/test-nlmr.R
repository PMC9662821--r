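test_that("residual stratification centers on the score and keeps the eGFR scale", {
  set.seed(31)
  n <- 500
  score <- rnorm(n)
  egfr <- 90 + 0.2 * score * 15 + rnorm(n, 0, 15)
  d <- data.frame(score = score, egfr = egfr)
  out <- residual_stratify(d)
  ## at the mean score, residual equals the exposure
  slope <- coef(lm(egfr ~ I(score - mean(score))))[2]
  expect_equal(out$residual, egfr - slope * (score - mean(score)),
               tolerance = 1e-10)
  expect_equal(length(levels(out$stratum)), 14)
  ## a participant with exposure 87 and score at the mean lands in [85,90)
  d2 <- rbind(d, data.frame(score = mean(score), egfr = 87))
  out2 <- residual_stratify(d2)
  expect_equal(as.character(out2$stratum[n + 1]), "[85,90)")
})

test_that("residual stratification errors on a negatively oriented score", {
  set.seed(32)
  score <- rnorm(300)
  d <- data.frame(score = score, egfr = 90 - 3 * score + rnorm(300))
  expect_error(residual_stratify(d), "orientation")
})

test_that("residual strata are nearly independent of the score", {
  cfg <- small_scenario(n_per_study = 20000, n_studies = 1, seed = 33)
  co <- simulate_cohort(cfg)
  rec <- co$participants
  rec$score <- rec$score_true
  out <- residual_stratify(rec)
  dummies <- model.matrix(~ stratum - 1, out)
  cors <- suppressWarnings(cor(out$score, dummies))
  expect_lt(max(abs(cors), na.rm = TRUE), 0.02)
})

test_that("doubly-ranked stratification matches an exhaustive 9-row check", {
  score <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  expo  <- c(5, 3, 9, 1, 8, 2, 7, 4, 6)
  st <- doubly_ranked_stratify(score, expo, 3)
  ## brute force: pre-strata by score {1,2,3},{4,5,6},{7,8,9}; within each,
  ## exposure rank decides the stratum
  brute <- integer(9)
  for (b in 0:2) {
    idx <- order(score)[(3 * b + 1):(3 * b + 3)]
    brute[idx[order(expo[idx])]] <- 1:3
  }
  expect_equal(st, brute)
  expect_equal(unname(table(st)), rep(3L, 3), ignore_attr = TRUE)
  means <- tapply(expo, st, mean)
  expect_true(all(diff(means) > 0))
})

test_that("doubly-ranked degenerates to within-block score ranks under monotone exposure", {
  set.seed(34)
  score <- rnorm(90)
  expo <- 2 * score + 1  # strictly increasing in score
  st <- doubly_ranked_stratify(score, expo, 3)
  ## with exposure monotone in score, the exposure rank within each
  ## score-sorted pre-stratum is the score rank within that block
  expected <- integer(90)
  expected[order(score)] <- rep(1:3, times = 30)
  expect_equal(st, expected)
  expect_equal(unname(table(st)), rep(30L, 3), ignore_attr = TRUE)
  means <- tapply(expo, st, mean)
  expect_true(all(diff(means) > 0))
  ## determinism with ties broken by input order
  score2 <- rep(1, 25); expo2 <- runif(25)
  expect_identical(doubly_ranked_stratify(score2, expo2, 5),
                   doubly_ranked_stratify(score2, expo2, 5))
  expect_error(doubly_ranked_stratify(score, expo, 1), "at least 2")
  expect_error(doubly_ranked_stratify(rnorm(8), rnorm(8), 3), "n_strata")
})

test_that("the LACE ratio follows its definition and flags weak instruments", {
  set.seed(35)
  n <- 400
  g <- rnorm(n)
  x <- 90 + 0.2 * g + rnorm(n, 0, 2)
  y <- rbinom(n, 1, 0.2)
  d <- data.frame(score = g, egfr = x, event = y)
  est <- estimate_lace(d, min_n = 100, min_events = 10)
  expect_equal(est$lace, est$beta_yg / est$beta_xg, tolerance = 1e-12)
  expect_equal(est$se, est$se_yg / abs(est$beta_xg), tolerance = 1e-12)
  expect_equal(est$per5_or, exp(-5 * est$lace), tolerance = 1e-12)
  ## direct arithmetic of the ratio definition
  expect_equal(-0.004 / 0.2, -0.02)
  expect_equal(exp(-5 * -0.02), exp(0.1))
  ## tiny first-stage slope trips the weak-instrument flag
  d2 <- d; d2$egfr <- 90 + 0.001 * g + rnorm(n, 0, 20)
  est2 <- tryCatch(estimate_lace(d2), error = function(e) NULL)
  if (!is.null(est2)) expect_true(est2$weak_instrument)
  expect_error(estimate_lace(d[1:50, ]), "floor")
})

test_that("ratio LACE equals two-stage least squares for continuous outcomes", {
  set.seed(36)
  n <- 600
  g <- rnorm(n)
  u <- rnorm(n)
  covs <- data.frame(age = rnorm(n, 55, 5), pc1 = rnorm(n))
  x <- 90 + 1.5 * g + 2 * u + 0.1 * covs$age + rnorm(n)
  y <- -0.03 * x + 0.5 * u + 0.02 * covs$pc1 + rnorm(n, 0, 0.5)
  d <- data.frame(score = g, egfr = x, yc = y, covs)
  est <- estimate_lace(d, outcome_col = "yc", covariates = c("age", "pc1"),
                       outcome_type = "continuous", min_n = 100)
  oracle <- tsls_slope(y, x, g, covs)
  expect_equal(est$lace, oracle, tolerance = 1e-8)
})

test_that("LACE recovers a known causal log-odds slope with coverage", {
  set.seed(37)
  true_slope <- -0.028
  hits <- logical(100)
  for (r in 1:100) {
    n <- 3000
    g <- rnorm(n)
    x <- 60 + 3 * g + rnorm(n, 0, 4)   # one stratum-like band
    y <- rbinom(n, 1, plogis(-1.5 + true_slope * (x - 60)))
    d <- data.frame(score = g, egfr = x, event = y)
    e <- estimate_lace(d)
    hits[r] <- abs(e$lace - true_slope) <= 1.96 * e$se
  }
  expect_gte(sum(hits), 90)
})

test_that("fixed-effect pooling of strata matches the closed form and checks levels", {
  est <- data.frame(study = rep(c("A", "B"), each = 2),
                    stratum = factor(rep(c("s1", "s2"), 2)),
                    lace = c(0.1, 0.3, 0.1, 0.5),
                    se = c(0.1, 0.2, 0.1, 0.1),
                    n = c(100, 100, 200, 150),
                    events = c(10, 12, 30, 20),
                    mean_exposure = c(50, 70, 52, 71),
                    x_lo = c(45, 65, 46, 66), x_hi = c(55, 75, 56, 76))
  pl <- pool_strata(est)
  expect_equal(nrow(pl), 2)
  s1 <- pl[pl$stratum == "s1", ]
  expect_equal(s1$lace, 0.1, tolerance = 1e-12)
  expect_equal(s1$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(s1$mean_exposure, (50 * 100 + 52 * 200) / 300)
  ## single-study stratum passes through
  one <- pool_strata(est[est$study == "A", ])
  expect_equal(one$lace, c(0.1, 0.3))
  ## disjoint label sets across studies signal clashing stratification schemes
  est2 <- est
  est2$stratum <- as.character(est2$stratum)
  est2$stratum[est2$study == "B"] <- c("t1", "t2")
  expect_error(pool_strata(est2), "mismatched stratum definitions")
})

test_that("piecewise curve integrates stratum slopes from the reference", {
  pl <- data.frame(stratum = c("a", "b"), lace = c(0, 0.01),
                   se = c(0.001, 0.001), n = c(100, 100),
                   mean_exposure = c(87.5, 92.5),
                   x_lo = c(85, 90), x_hi = c(90, 95))
  cv <- build_piecewise_curve(pl, B = 200, seed = 1)
  expect_equal(cv$log_hr[cv$egfr == 90], 0)
  expect_equal(cv$log_hr[cv$egfr == 95], 0.05, tolerance = 1e-12)
  expect_equal(cv$log_hr[cv$egfr == 85], 0, tolerance = 1e-12)
  expect_true(all(cv$ci_low <= cv$log_hr & cv$log_hr <= cv$ci_high))
  ## zero SEs collapse the CI onto the point curve
  pl0 <- pl; pl0$se <- c(1e-12, 1e-12)
  cv0 <- build_piecewise_curve(pl0, B = 150, seed = 2)
  expect_equal(cv0$ci_low, cv0$log_hr, tolerance = 1e-8)
  expect_equal(cv0$ci_high, cv0$log_hr, tolerance = 1e-8)
  expect_error(build_piecewise_curve(pl, B = 50), "at least 100")
})

test_that("curve is continuous and reproducible under a fixed seed", {
  set.seed(38)
  K <- 6
  pl <- data.frame(stratum = letters[1:K],
                   lace = rnorm(K, 0, 0.05), se = runif(K, 0.01, 0.05),
                   n = rep(100, K),
                   mean_exposure = seq(60, 110, length.out = K),
                   x_lo = seq(55, 105, length.out = K),
                   x_hi = seq(65, 115, length.out = K))
  cv1 <- build_piecewise_curve(pl, B = 300, seed = 9)
  cv2 <- build_piecewise_curve(pl, B = 300, seed = 9)
  expect_identical(cv1, cv2)
  jumps <- abs(diff(cv1$log_hr))
  expect_lt(max(jumps), max(abs(pl$lace)) * 1.5 + 1e-12)
})

test_that("trend tests behave at the null and under a constructed trend", {
  pl_id <- data.frame(lace = rep(0.1, 4), se = rep(0.05, 4),
                      mean_exposure = c(50, 60, 70, 80))
  tt <- lace_trend_tests(pl_id)
  expect_equal(tt$Q, 0, tolerance = 1e-12)
  expect_equal(tt$trend_slope, 0, tolerance = 1e-12)

  pl_tr <- data.frame(lace = 0.002 * c(50, 60, 70, 80) - 0.1,
                      se = rep(1e-4, 4),
                      mean_exposure = c(50, 60, 70, 80))
  tt2 <- lace_trend_tests(pl_tr)
  expect_lt(tt2$p_trend, 1e-6)
  expect_error(lace_trend_tests(pl_id[1:2, ]), "at least 3")
})

test_that("residual and doubly-ranked stratification agree on the pooled LACE", {
  cfg <- small_scenario(n_per_study = 15000, n_studies = 2, seed = 39)
  co <- simulate_cohort(cfg)
  rec <- eligibility_filter(co$participants)$records
  co$participants <- rec
  co$genotypes <- co$genotypes[match(rec$id, rownames(co$genotypes)), ,
                               drop = FALSE]
  r1 <- mr_chain(co)$per_study
  r2 <- mr_chain(co, stratification = "doubly_ranked", n_strata = 10)$per_study
  f1 <- fixed_effect(r1$lace, r1$se)
  f2 <- fixed_effect(r2$lace, r2$se)
  expect_lt(abs(f1$estimate - f2$estimate),
            sqrt(f1$se^2 + f2$se^2))
})
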