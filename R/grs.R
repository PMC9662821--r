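## Genetic risk score construction and characterization.

#' Filter variants by exclusion flags
#'
#' Removes any variant with at least one raised exclusion flag
#' (`flag_ancestry`: ancestry heterogeneity; `flag_riskfactor`: genome-wide
#' association with a vascular risk factor; `flag_missing`: missing in at
#' least one contributing study). A variant with several raised flags counts
#' once in the retained/removed totals but is attributed to every flag it
#' raises in the per-flag tallies.
#'
#' @param weights Data frame with columns `variant_id`, `effect_allele`,
#'   `weight`, `flag_ancestry`, `flag_riskfactor`, `flag_missing`.
#' @return List with `retained` (filtered data frame), `n_input`,
#'   `n_retained`, `n_removed` and `flag_counts` (named integer vector).
#' @export
filter_variants <- function(weights) {
  stopifnot(is.data.frame(weights))
  need <- c("variant_id", "weight", "flag_ancestry", "flag_riskfactor",
            "flag_missing")
  assert_that(all(need %in% names(weights)),
              "weights lacks columns: %s",
              paste(setdiff(need, names(weights)), collapse = ", "))
  assert_that(!anyDuplicated(weights$variant_id),
              "duplicate variant_id in weights table")
  assert_that(all(is.finite(weights$weight)), "weights must be finite")
  flags <- as.matrix(weights[, c("flag_ancestry", "flag_riskfactor",
                                 "flag_missing")])
  storage.mode(flags) <- "logical"
  drop <- rowSums(flags, na.rm = TRUE) > 0
  list(retained = weights[!drop, , drop = FALSE],
       n_input = nrow(weights),
       n_retained = sum(!drop),
       n_removed = sum(drop),
       flag_counts = c(ancestry  = sum(flags[, "flag_ancestry"], na.rm = TRUE),
                       riskfactor = sum(flags[, "flag_riskfactor"], na.rm = TRUE),
                       missing   = sum(flags[, "flag_missing"], na.rm = TRUE)))
}

#' Compute a weighted genetic risk score
#'
#' `score_i = sum_j w_j g_ij`, where `g_ij` is the dosage of the effect allele
#' of variant `j` in participant `i`. If the genotype matrix carries a
#' `coded_allele` attribute (named by variant), dosages coded on the opposite
#' allele are flipped (`2 - g`) before summation so that all contributions are
#' on the effect-allele scale.
#'
#' @param genotypes Numeric matrix, participants x variants, dosages in
#'   \[0, 2\], with variant ids as column names; optional attribute
#'   `coded_allele` (named character vector).
#' @param weights Data frame of retained variants (see [filter_variants()]).
#' @return Numeric vector of per-participant scores (eGFR units when weights
#'   are in eGFR units per allele).
#' @export
compute_grs <- function(genotypes, weights) {
  stopifnot(is.matrix(genotypes), is.data.frame(weights))
  assert_that(!is.null(colnames(genotypes)), "genotypes must have variant ids as colnames")
  absent <- setdiff(weights$variant_id, colnames(genotypes))
  assert_that(length(absent) == 0,
              "retained variants absent from genotype matrix: %s",
              paste(head(absent, 5), collapse = ", "))
  g <- genotypes[, weights$variant_id, drop = FALSE]
  assert_that(!anyNA(g), "genotype matrix contains missing dosages")
  assert_that(all(g >= 0 & g <= 2), "dosages must lie in [0, 2]")
  coded <- attr(genotypes, "coded_allele")
  w <- weights$weight
  if (!is.null(coded) && "effect_allele" %in% names(weights)) {
    flip <- coded[weights$variant_id] != weights$effect_allele
    flip[is.na(flip)] <- FALSE
    if (any(flip)) {
      ## dosage of the effect allele is 2 - coded dosage
      g[, flip] <- 2 - g[, flip]
    }
  }
  drop(g %*% w)
}

#' Variance in an exposure explained by a genetic score
#'
#' Reports (i) `r2`, the incremental R-squared of adding the score to a
#' covariate-only linear model of the exposure, and (ii) `sd_slope`, the
#' univariable regression slope of the standardized exposure on the
#' standardized score (SD exposure per SD score). In the univariable case
#' `sd_slope^2 == r2` up to floating point.
#'
#' @param score Numeric vector of per-participant scores.
#' @param exposure Numeric vector (same length), e.g. eGFR.
#' @param covariates Optional data frame of adjustment covariates.
#' @return Object of class `score_summary`: list with `r2`, `sd_slope`, `n`,
#'   and the standardized score.
#' @export
variance_explained <- function(score, exposure, covariates = NULL) {
  assert_that(length(score) == length(exposure),
              "score and exposure lengths differ")
  n <- length(score)
  assert_that(n >= 30, "need at least 30 observations")
  if (sd(score) == 0) {
    warning("score has zero variance; r2 set to 0")
    out <- list(r2 = 0, sd_slope = 0, n = n,
                standardized_score = rep(0, n))
    class(out) <- "score_summary"
    return(out)
  }
  zs <- as.numeric(scale(score))
  zx <- as.numeric(scale(exposure))
  sd_slope <- unname(coef(lm(zx ~ zs))[2])
  if (is.null(covariates)) {
    r2 <- summary(lm(exposure ~ score))$r.squared
  } else {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    d0 <- data.frame(exposure = exposure, covariates)
    d1 <- data.frame(exposure = exposure, score = score, covariates)
    r2 <- summary(lm(exposure ~ ., data = d1))$r.squared -
      summary(lm(exposure ~ ., data = d0))$r.squared
  }
  out <- list(r2 = r2, sd_slope = sd_slope, n = n, standardized_score = zs)
  class(out) <- "score_summary"
  out
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("Score summary (n = %d): incremental R^2 = %.4f, SD slope = %.3f\n",
              x$n, x$r2, x$sd_slope))
  invisible(x)
}

#' Scan traits for association with a genetic score
#'
#' Regresses each trait on the standardized score (linear for numeric traits,
#' logistic for binary traits), adjusting for covariates. Reports per-trait
#' coefficients per SD of score with 95% CIs, p-values, and a Bonferroni
#' significance flag across the scanned traits.
#'
#' @param score Numeric score vector.
#' @param traits Data frame of traits (numeric or two-level).
#' @param covariates Optional data frame of adjustment covariates.
#' @param alpha Family-wise significance level for the Bonferroni flag.
#' @return Data frame: trait, type, n, beta, se, ci_low, ci_high, p,
#'   bonferroni_sig; attribute `adjustment = "bonferroni"`. Constant traits
#'   are skipped (recorded with NA estimates and type "skipped").
#' @export
association_scan <- function(score, traits, covariates = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(traits))
  zs <- as.numeric(scale(score))
  k <- ncol(traits)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    tr <- traits[[j]]
    nm <- names(traits)[j]
    if (is.character(tr) || is.factor(tr)) tr <- factor(tr)
    uv <- unique(tr[!is.na(tr)])
    if (length(uv) < 2) {
      rows[[j]] <- data.frame(trait = nm, type = "skipped", n = NA_integer_,
                              beta = NA_real_, se = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_)
      next
    }
    binary <- (is.factor(tr) && nlevels(tr) == 2) ||
      (is.numeric(tr) && length(uv) == 2 && all(uv %in% c(0, 1))) ||
      is.logical(tr)
    y <- if (is.factor(tr)) as.integer(tr) - 1L else as.numeric(tr)
    d <- data.frame(y = y, zs = zs)
    if (!is.null(covariates)) d <- cbind(d, covariates)
    fit <- tryCatch(
      if (binary) glm(y ~ ., data = d, family = binomial())
      else lm(y ~ ., data = d),
      warning = function(w) suppressWarnings(
        if (binary) glm(y ~ ., data = d, family = binomial())
        else lm(y ~ ., data = d)))
    sm <- summary(fit)$coefficients
    if (!("zs" %in% rownames(sm)) || !is.finite(sm["zs", 2])) {
      rows[[j]] <- data.frame(trait = nm, type = "skipped", n = NA_integer_,
                              beta = NA_real_, se = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_,
                              p = NA_real_)
      next
    }
    b <- sm["zs", 1]; s <- sm["zs", 2]
    rows[[j]] <- data.frame(
      trait = nm, type = if (binary) "binary" else "continuous",
      n = sum(!is.na(y)), beta = b, se = s,
      ci_low = b - qnorm(0.975) * s, ci_high = b + qnorm(0.975) * s,
      p = 2 * pnorm(-abs(b / s)))
  }
  out <- do.call(rbind, rows)
  m <- sum(out$type != "skipped")
  out$bonferroni_sig <- !is.na(out$p) & out$p < alpha / max(m, 1)
  attr(out, "adjustment") <- "bonferroni"
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}
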