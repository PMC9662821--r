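## Nonlinear Mendelian randomization: stratification (residual and
## doubly-ranked), per-stratum localized average causal effects (LACE) by the
## ratio method, fixed-effect pooling across studies, and reconstruction of
## the piecewise-linear causal curve with resampled pointwise CIs.

#' Default residual-eGFR stratum boundaries
#'
#' 5-unit categories between 45 and 105 plus open tails, giving 14 strata:
#' `<45`, `[45,50)`, ..., `[100,105)`, `>=105`.
#' @return Numeric vector of interior breakpoints.
#' @export
default_strata_breaks <- function() seq(45, 105, by = 5)

stratum_labels <- function(breaks) {
  k <- length(breaks)
  c(sprintf("<%g", breaks[1]),
    sprintf("[%g,%g)", breaks[-k], breaks[-1]),
    sprintf(">=%g", breaks[k]))
}

#' Residual-method stratification
#'
#' For each study, regresses the exposure on the centered genetic score
#' (plus optional covariates), computes the residual exposure
#' `exposure - slope * (score - mean(score))` (which keeps the eGFR scale),
#' and assigns participants to strata by residual exposure. Stratifying on
#' the residual keeps stratum membership approximately independent of the
#' instrument under a homogeneous linear score-exposure effect.
#'
#' @param data Data frame with the exposure and score columns (and optionally
#'   a `study` column; the regression is run per study).
#' @param score_col,exposure_col Column names (defaults `"score"`, `"egfr"`).
#' @param covariates Optional character vector of extra regression terms.
#' @param breaks Interior stratum breakpoints (default
#'   [default_strata_breaks()]).
#' @return `data` with added columns `residual` and `stratum` (ordered
#'   factor over all 14 levels).
#' @export
residual_stratify <- function(data, score_col = "score",
                              exposure_col = "egfr",
                              covariates = character(0),
                              breaks = default_strata_breaks()) {
  stopifnot(is.data.frame(data))
  score <- data[[score_col]]
  expo <- data[[exposure_col]]
  assert_that(!is.null(score) && !is.null(expo),
              "score/exposure columns not found")
  assert_that(!anyNA(score) && !anyNA(expo),
              "score and exposure must be complete")
  studies <- if ("study" %in% names(data)) data$study else rep("all", nrow(data))
  residual <- numeric(nrow(data))
  for (s in unique(studies)) {
    i <- which(studies == s)
    sc <- score[i] - mean(score[i])
    d <- data.frame(.y = expo[i], .s = sc)
    rhs <- c(".s", covariates)
    if (length(covariates)) d <- cbind(d, data[i, , drop = FALSE])
    fit <- lm(as.formula(paste(".y ~", paste(rhs, collapse = " + "))), data = d)
    slope <- coef(fit)[[".s"]]
    assert_that(is.finite(slope) && slope > 0,
                "score does not positively predict exposure in study '%s' (slope %.3g); check score orientation",
                s, slope)
    residual[i] <- expo[i] - slope * sc
  }
  labs <- stratum_labels(breaks)
  data$residual <- residual
  data$stratum <- cut(residual, c(-Inf, breaks, Inf), labels = labs,
                      right = FALSE, ordered_result = TRUE)
  data
}

#' Doubly-ranked stratification
#'
#' Non-parametric stratification: sort by the instrument (score), form
#' consecutive pre-strata of size `n_strata`, rank members of each
#' pre-stratum by exposure, and send the q-th ranked member to stratum q.
#' Any remainder pre-stratum is distributed by the same rank rule. Ties in
#' score or exposure are broken by stable input order, so repeated runs are
#' deterministic.
#'
#' @param score Numeric instrument values.
#' @param exposure Numeric exposure values (same length).
#' @param n_strata Number of strata (>= 2); requires `n >= n_strata^2`.
#' @return Integer vector of stratum assignments in 1..n_strata.
#' @export
doubly_ranked_stratify <- function(score, exposure, n_strata) {
  n <- length(score)
  assert_that(length(exposure) == n, "score/exposure lengths differ")
  assert_that(n_strata >= 2, "n_strata must be at least 2")
  assert_that(n >= n_strata^2, "need n >= n_strata^2 observations")
  ord <- order(score)  # stable for ties
  pre <- (seq_len(n) - 1L) %/% n_strata + 1L  # pre-strata of size n_strata
  stratum <- integer(n)
  for (b in unique(pre)) {
    idx <- ord[pre == b]
    r <- order(exposure[idx])  # stable rank by exposure
    stratum[idx[r]] <- seq_along(idx)
  }
  stratum
}

#' Localized average causal effect in one stratum (ratio method)
#'
#' Within a stratum, estimates the instrument-outcome association `beta_yg`
#' (logistic regression of incident case status on the score, or linear
#' regression for a continuous outcome) and the instrument-exposure
#' association `beta_xg` (linear regression), both adjusted for the same
#' covariates, and forms the ratio estimate
#' `LACE = beta_yg / beta_xg` (log-odds per exposure unit) with first-order
#' delta-method standard error `SE(beta_yg)/|beta_xg|`. The odds ratio per 5
#' units lower exposure is `exp(-5 * LACE)`.
#'
#' @param data Stratum data frame.
#' @param score_col,exposure_col,outcome_col Column names.
#' @param covariates Character vector of adjustment terms (e.g.
#'   `c("age", "I(age^2)", "sex", "center", paste0("pc", 1:10))`).
#' @param outcome_type `"binary"` (logistic `beta_yg`) or `"continuous"`
#'   (linear; then the ratio equals two-stage least squares).
#' @param min_n,min_events Floors below which the stratum is rejected.
#' @param second_order If TRUE, add the second-order delta-method term
#'   `beta_yg^2 Var(beta_xg) / beta_xg^4` to the variance.
#' @param weak_z Threshold on `|beta_xg|/SE(beta_xg)` under which a
#'   weak-instrument flag is attached.
#' @return One-row data frame: `n`, `events`, `mean_exposure`, `x_lo`/`x_hi`
#'   (central 90% exposure range), `beta_xg`, `se_xg`, `beta_yg`, `se_yg`,
#'   `lace`, `se`, `per5_or`, `per5_ci_low`, `per5_ci_high`,
#'   `weak_instrument`.
#' @export
estimate_lace <- function(data, score_col = "score", exposure_col = "egfr",
                          outcome_col = "event",
                          covariates = character(0),
                          outcome_type = c("binary", "continuous"),
                          min_n = 100, min_events = 10,
                          second_order = FALSE, weak_z = 2) {
  outcome_type <- match.arg(outcome_type)
  n <- nrow(data)
  assert_that(n >= min_n, "stratum has %d rows; floor is %d", n, min_n)
  y <- data[[outcome_col]]
  x <- data[[exposure_col]]
  g <- data[[score_col]]
  assert_that(!is.null(y) && !is.null(x) && !is.null(g),
              "score/exposure/outcome columns not found")
  events <- if (outcome_type == "binary") sum(y) else NA_real_
  if (outcome_type == "binary")
    assert_that(events >= min_events, "stratum has %g events; floor is %d",
                events, min_events)
  rhs <- paste(c(score_col, covariates), collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), data = data)
  jg <- match(score_col, colnames(X))
  ## instrument-exposure slope (linear); mind QR column pivoting
  fx <- lm.fit(X, x)
  p <- fx$rank
  XtXinv <- chol2inv(fx$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  jx <- match(jg, fx$qr$pivot[seq_len(p)])
  assert_that(!is.na(jx), "score column aliased in the design matrix")
  sig2 <- sum(fx$residuals^2) / (n - p)
  beta_xg <- fx$coefficients[[jg]]
  se_xg <- sqrt(sig2 * XtXinv[jx, jx])
  assert_that(is.finite(beta_xg) && beta_xg != 0,
              "instrument-exposure association is zero")
  ## instrument-outcome slope
  if (outcome_type == "binary") {
    fy <- suppressWarnings(glm.fit(X, y, family = binomial()))
    py <- fy$rank
    Vy <- chol2inv(fy$qr$qr[seq_len(py), seq_len(py), drop = FALSE])
    jy <- match(jg, fy$qr$pivot[seq_len(py)])
    beta_yg <- fy$coefficients[[jg]]
    se_yg <- sqrt(Vy[jy, jy])
  } else {
    fy <- lm.fit(X, y)
    beta_yg <- fy$coefficients[[jg]]
    sig2y <- sum(fy$residuals^2) / (n - p)
    se_yg <- sqrt(sig2y * XtXinv[jx, jx])
  }
  lace <- beta_yg / beta_xg
  v <- (se_yg / beta_xg)^2
  if (second_order) v <- v + beta_yg^2 * se_xg^2 / beta_xg^4
  se <- sqrt(v)
  z <- qnorm(0.975)
  qx <- quantile(x, c(0.05, 0.95), names = FALSE)
  data.frame(
    n = n, events = events, mean_exposure = mean(x),
    x_lo = qx[1], x_hi = qx[2],
    beta_xg = beta_xg, se_xg = se_xg, beta_yg = beta_yg, se_yg = se_yg,
    lace = lace, se = se,
    per5_or = exp(-5 * lace),
    per5_ci_low = exp(-5 * lace - z * 5 * se),
    per5_ci_high = exp(-5 * lace + z * 5 * se),
    weak_instrument = abs(beta_xg) / se_xg < weak_z)
}

#' Per-stratum LACE estimates for one study
#'
#' Loops [estimate_lace()] over the levels of a stratum column, silently
#' skipping strata that fail the size/event floors.
#'
#' @param data Data frame with a `stratum` column (factor).
#' @inheritParams estimate_lace
#' @param stratum_col Name of the stratum column.
#' @return Data frame with one row per estimable stratum, carrying a
#'   `stratum` column; attribute `skipped` lists strata below the floors.
#' @export
stratum_estimates <- function(data, stratum_col = "stratum",
                              score_col = "score", exposure_col = "egfr",
                              outcome_col = "event",
                              covariates = character(0),
                              outcome_type = c("binary", "continuous"),
                              min_n = 100, min_events = 10,
                              second_order = FALSE) {
  outcome_type <- match.arg(outcome_type)
  st <- data[[stratum_col]]
  assert_that(!is.null(st), "stratum column '%s' not found", stratum_col)
  st <- as.factor(st)
  rows <- list(); skipped <- character(0)
  for (lv in levels(st)) {
    d <- data[st == lv, , drop = FALSE]
    ok_floor <- nrow(d) >= min_n &&
      (outcome_type != "binary" || sum(d[[outcome_col]]) >= min_events)
    if (!ok_floor) { skipped <- c(skipped, lv); next }
    est <- tryCatch(
      estimate_lace(d, score_col, exposure_col, outcome_col, covariates,
                    outcome_type, min_n, min_events, second_order),
      error = function(e) NULL)
    if (is.null(est)) { skipped <- c(skipped, lv); next }
    est$stratum <- lv
    rows[[length(rows) + 1]] <- est
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0))
  if (nrow(out)) {
    out$stratum <- factor(out$stratum, levels = levels(st))
    out <- out[order(out$stratum), c("stratum",
                                     setdiff(names(out), "stratum"))]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  attr(out, "stratum_levels") <- levels(st)
  out
}

#' Pool stratum estimates across studies (fixed-effect)
#'
#' Inverse-variance fixed-effect pooling of the LACE within each stratum
#' across studies. Pooled `mean_exposure` (and the exposure span used for
#' curve construction) is the n-weighted mean of the study values; `n` and
#' `events` are summed.
#'
#' @param estimates Data frame of per-study stratum estimates (as from
#'   [stratum_estimates()]) with an added `study` column; all studies must
#'   share the same stratum level set.
#' @return Data frame with one row per stratum present in at least one
#'   study: `stratum`, `k` (studies), `n`, `events`, `mean_exposure`,
#'   `x_lo`, `x_hi`, `lace`, `se`, `Q`, `per5_or`, `per5_ci_low`,
#'   `per5_ci_high`.
#' @export
pool_strata <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  assert_that(all(c("study", "stratum", "lace", "se", "n") %in%
                    names(estimates)), "estimates lacks required columns")
  ## stratum definitions must agree across studies: two studies whose label
  ## sets are disjoint were stratified under different schemes
  per_study <- split(as.character(estimates$stratum), estimates$study)
  if (length(per_study) > 1) {
    for (i in seq_along(per_study)) for (j in seq_len(i - 1)) {
      assert_that(length(intersect(per_study[[i]], per_study[[j]])) > 0,
                  "mismatched stratum definitions across studies ('%s' vs '%s')",
                  names(per_study)[i], names(per_study)[j])
    }
  }
  lv <- if (is.factor(estimates$stratum)) levels(estimates$stratum) else
    unique(as.character(estimates$stratum))
  z <- qnorm(0.975)
  rows <- lapply(intersect(lv, as.character(estimates$stratum)), function(s) {
    e <- estimates[as.character(estimates$stratum) == s, , drop = FALSE]
    fe <- fixed_effect(e$lace, e$se)
    data.frame(
      stratum = s, k = nrow(e), n = sum(e$n),
      events = if ("events" %in% names(e)) sum(e$events) else NA_real_,
      mean_exposure = weighted.mean(e$mean_exposure, e$n),
      x_lo = if ("x_lo" %in% names(e)) weighted.mean(e$x_lo, e$n) else NA_real_,
      x_hi = if ("x_hi" %in% names(e)) weighted.mean(e$x_hi, e$n) else NA_real_,
      lace = fe$estimate, se = fe$se, Q = fe$Q,
      per5_or = exp(-5 * fe$estimate),
      per5_ci_low = exp(-5 * fe$estimate - z * 5 * fe$se),
      per5_ci_high = exp(-5 * fe$estimate + z * 5 * fe$se))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_exposure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Piecewise-linear curve value: integral of segment slopes from `ref`.
## bounds: length K+1 nondecreasing; slopes: length K; terminal slopes
## extrapolate beyond the outer bounds.
piecewise_value <- function(x, bounds, slopes, ref) {
  node <- cumsum(c(0, slopes * diff(bounds)))  # value at bounds, up to a constant
  idx <- findInterval(x, bounds, all.inside = TRUE)
  val <- node[idx] + slopes[idx] * (x - bounds[idx])
  idr <- findInterval(ref, bounds, all.inside = TRUE)
  val - (node[idr] + slopes[idr] * (ref - bounds[idr]))
}

#' Piecewise-linear causal curve from pooled stratum estimates
#'
#' Builds the nonlinear MR dose-response curve: within each stratum's
#' exposure span the curve has slope equal to that stratum's pooled LACE,
#' and the curve integrates the slopes outward from the reference (value 0
#' at the reference, by construction, in every resampling draw). Each
#' stratum spans the central 90% of its members' observed exposure, abutted
#' to its neighbors at midpoints. Pointwise 95% CIs come from `B`
#' independent normal resamples of each stratum's LACE.
#'
#' @param pooled Data frame from [pool_strata()] (ordered by exposure).
#' @param reference Reference exposure (default 90); must lie inside the
#'   covered range.
#' @param B Number of resampling draws (>= 100).
#' @param seed Optional integer seed for the resampling.
#' @param grid Optional evaluation grid; default: unit steps over the
#'   covered range plus the reference.
#' @return Object of class `lace_curve` (and `curve_estimate`): data frame
#'   `egfr`, `log_hr`, `ci_low`, `ci_high`, with attributes `strata`
#'   (pooled table with segment bounds), `reference`, `B`.
#' @export
build_piecewise_curve <- function(pooled, reference = 90, B = 1000,
                                  seed = NULL, grid = NULL) {
  stopifnot(is.data.frame(pooled))
  assert_that(B >= 100, "B must be at least 100 for stable percentiles")
  assert_that(nrow(pooled) >= 1, "no pooled strata")
  p <- pooled[order(pooled$mean_exposure), , drop = FALSE]
  K <- nrow(p)
  ## abutting segment bounds from the central-90% spans
  bounds <- numeric(K + 1)
  bounds[1] <- p$x_lo[1]
  if (K > 1) bounds[2:K] <- (p$x_hi[-K] + p$x_lo[-1]) / 2
  bounds[K + 1] <- p$x_hi[K]
  bounds <- cummax(bounds)
  assert_that(reference >= bounds[1] && reference <= bounds[K + 1],
              "reference %g outside covered exposure range [%g, %g]",
              reference, bounds[1], bounds[K + 1])
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(ceiling(bounds[1]), floor(bounds[K + 1])),
                          reference)))
  }
  est <- piecewise_value(grid, bounds, p$lace, reference)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  draws <- matrix(rnorm(B * K, mean = rep(p$lace, each = B),
                        sd = rep(p$se, each = B)), nrow = B)
  curves <- apply(draws, 1, function(sl)
    piecewise_value(grid, bounds, sl, reference))
  ci <- apply(curves, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- new_curve_estimate(grid, est, ci[1, ], ci[2, ], reference,
                            kind = "mr_piecewise")
  p$seg_low <- bounds[-(K + 1)]
  p$seg_high <- bounds[-1]
  attr(out, "strata") <- p
  attr(out, "B") <- B
  class(out) <- c("lace_curve", class(out))
  out
}

## save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Heterogeneity and trend tests across stratum LACEs
#'
#' Cochran's Q for heterogeneity of the pooled stratum LACEs and an
#' inverse-variance-weighted meta-regression of LACE on mean stratum
#' exposure (linear trend), with p-values.
#'
#' @param pooled Data frame from [pool_strata()] with at least 3 strata.
#' @return List: `Q`, `df`, `p_heterogeneity`, `trend_slope`, `trend_se`,
#'   `p_trend`.
#' @export
lace_trend_tests <- function(pooled) {
  stopifnot(is.data.frame(pooled))
  k <- nrow(pooled)
  assert_that(k >= 3, "need at least 3 strata; got %d", k)
  w <- 1 / pooled$se^2
  fe <- sum(w * pooled$lace) / sum(w)
  Q <- sum(w * (pooled$lace - fe)^2)
  X <- cbind(1, pooled$mean_exposure)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  b <- drop(V %*% crossprod(X, w * pooled$lace))
  se_b <- sqrt(V[2, 2])
  list(Q = Q, df = k - 1, p_heterogeneity = pchisq(Q, k - 1, lower.tail = FALSE),
       trend_slope = b[2], trend_se = se_b,
       p_trend = 2 * pnorm(-abs(b[2] / se_b)))
}
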