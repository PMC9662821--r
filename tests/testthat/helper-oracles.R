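## Independent oracles and small fixtures used across the test files.
## These deliberately re-derive quantities from first principles (explicit
## likelihoods, elementwise sums, closed forms) rather than calling the
## package's own code paths.

## Breslow partial log-likelihood for a single-stratum Cox model,
## written out directly from its definition.
breslow_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

## Maximize the written-out partial likelihood by general-purpose
## optimization (independent of survival::coxph internals).
brute_force_cox <- function(time, event, X) {
  X <- as.matrix(X)
  opt <- optim(rep(0, ncol(X)),
               function(b) -breslow_loglik(b, time, event, X),
               method = "BFGS", control = list(reltol = 1e-14))
  opt$par
}

## Two-stage least squares with a single excluded instrument, by the
## textbook matrix formula beta = (Z'X)^{-1} Z'y on the full systems.
tsls_slope <- function(y, x, z, covariates = NULL) {
  C <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  Xm <- cbind(x, C)
  Zm <- cbind(z, C)
  b <- solve(crossprod(Zm, Xm), crossprod(Zm, y))
  b[1]
}

## A toy variant-weight table with controllable flags.
toy_weights <- function(n = 6, flags = NULL) {
  w <- data.frame(variant_id = sprintf("v%03d", seq_len(n)),
                  effect_allele = rep(c("A", "C"), length.out = n),
                  weight = seq(-0.3, 0.3, length.out = n),
                  flag_ancestry = FALSE, flag_riskfactor = FALSE,
                  flag_missing = FALSE)
  if (!is.null(flags)) for (nm in names(flags)) w[[nm]][flags[[nm]]] <- TRUE
  w
}

## A small deterministic survival data set with sex/center strata.
toy_survival <- function(n = 60, seed = 42) {
  set.seed(seed)
  d <- data.frame(
    id = seq_len(n),
    x = rnorm(n), age = rnorm(n, 55, 6),
    sex = sample(c("male", "female"), n, replace = TRUE),
    center = sample(c("C1", "C2"), n, replace = TRUE))
  rate <- 0.1 * exp(0.5 * d$x)
  t_ev <- rexp(n, rate)
  d$time <- pmin(t_ev, 8)
  d$event <- as.integer(t_ev <= 8)
  d
}

## Reduced-size default scenario used by several suites: same calibration
## targets and causal curve as the full default, smaller n and variant count.
small_scenario <- function(n_per_study = 4000, n_studies = 2, seed = 1,
                           ...) {
  scenario_config(n_per_study = n_per_study, n_studies = n_studies,
                  n_variants = 16, seed = seed, ...)
}

mr_covariates <- c("age", "I(age^2)", "sex", "center", paste0("pc", 1:10))

## Run the MR chain (score -> residual strata -> per-study LACE -> pooled)
## on a simulated cohort; used by recovery/calibration suites.
mr_chain <- function(cohort, covariates = mr_covariates,
                     min_n = 50, min_events = 5,
                     stratification = "residual", n_strata = 10) {
  rec <- cohort$participants
  g <- cohort$genotypes[match(rec$id, rownames(cohort$genotypes)), ,
                        drop = FALSE]
  rec$score <- compute_grs(g, cohort$weights)
  rec$score_std <- ave(rec$score, rec$study,
                       FUN = function(z) (z - mean(z)) / sd(z))
  per_study <- lapply(split(rec, rec$study), function(d) {
    if (stratification == "residual") {
      d <- residual_stratify(d, score_col = "score_std")
    } else {
      d$stratum <- factor(doubly_ranked_stratify(d$score_std, d$egfr,
                                                 n_strata),
                          levels = seq_len(n_strata))
    }
    stratum_estimates(d, score_col = "score_std", covariates = covariates,
                      min_n = min_n, min_events = min_events)
  })
  est <- do.call(rbind, Map(function(e, s) {
    if (nrow(e)) e$study <- s
    e
  }, per_study, names(per_study)))
  list(records = rec, per_study = est, pooled = pool_strata(est))
}

## Inverse-variance pooled per-5-unit OR over a subset of strata.
pool_subset_or <- function(per_study, strata_keep) {
  e <- per_study[as.character(per_study$stratum) %in% strata_keep, ,
                 drop = FALSE]
  fe <- fixed_effect(e$lace, e$se)
  c(or = exp(-5 * fe$estimate),
    lo = exp(-5 * fe$estimate - 1.96 * 5 * fe$se),
    hi = exp(-5 * fe$estimate + 1.96 * 5 * fe$se))
}
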