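## Meta-analysis primitives shared by the observational and MR arms.

new_meta_result <- function(estimate, se, Q, tau2, k, method) {
  out <- list(estimate = estimate, se = se, Q = Q, tau2 = tau2, k = k,
              method = method,
              ci_low = estimate - qnorm(0.975) * se,
              ci_high = estimate + qnorm(0.975) * se)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s meta-analysis (k = %d): %.4f (SE %.4f), Q = %.3f, tau2 = %.4f\n",
              x$method, x$k, x$estimate, x$se, x$Q, x$tau2))
  invisible(x)
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools study estimates with weights `1/se^2`; pooled SE is
#' `(sum 1/se^2)^(-1/2)`. Cochran's Q is reported for reference.
#'
#' @param estimates Numeric vector of study estimates (k >= 1).
#' @param ses Positive standard errors.
#' @return A `meta_result` with `method = "fixed"` and `tau2 = 0`.
#' @export
fixed_effect <- function(estimates, ses) {
  k <- length(estimates)
  assert_that(k >= 1 && length(ses) == k, "need k >= 1 matching estimates/SEs")
  assert_that(all(is.finite(ses)) && all(ses > 0), "all SEs must be > 0")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - est)^2)
  new_meta_result(est, sqrt(1 / sum(w)), Q, 0, k, "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` with fixed-effect
#' weights `w = 1/se^2`, followed by re-weighted pooling with
#' `w* = 1/(se^2 + tau2)`.
#'
#' @inheritParams fixed_effect
#' @return A `meta_result` with `method = "dl_random"`.
#' @export
dersimonian_laird <- function(estimates, ses) {
  k <- length(estimates)
  assert_that(k >= 2 && length(ses) == k, "need k >= 2 matching estimates/SEs")
  assert_that(all(is.finite(ses)) && all(ses > 0), "all SEs must be > 0")
  w <- 1 / ses^2
  fe <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  new_meta_result(sum(ws * estimates) / sum(ws), sqrt(1 / sum(ws)),
                  Q, tau2, k, "dl_random")
}

## symmetric matrix square root (PSD input)
mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

## clip eigenvalues at zero to project onto the PSD cone
psd_clip <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
}

#' Multivariate random-effects meta-analysis (matrix method of moments)
#'
#' Pools per-study coefficient vectors with within-study covariances `S_i`
#' and a method-of-moments between-study covariance `Psi`. The moment
#' statistic is `Q = sum_i W_i^{1/2} r_i r_i' W_i^{1/2}` with fixed-effect
#' weights `W_i = S_i^{-1}` and GLS residuals `r_i`; `Psi` solves the linear
#' matrix equation `E[Q] = Q` and is truncated to positive semidefiniteness
#' by eigenvalue clipping. In dimension 1 the estimator reduces exactly to
#' DerSimonian-Laird. Pooling is then GLS with weights `(S_i + Psi)^{-1}`.
#'
#' Used to pool fractional-polynomial coefficient pairs across studies before
#' dose-response curve construction.
#'
#' @param estimates List of numeric vectors (equal length p), one per study.
#' @param covariances List of p x p positive-semidefinite matrices.
#' @param diagonal If TRUE, constrain `Psi` to be diagonal (each coordinate
#'   then follows its own univariate DerSimonian-Laird moment equation).
#' @return List of class `mv_meta_result`: `estimate` (pooled vector),
#'   `vcov` (pooled covariance), `psi` (between-study covariance), `Q`
#'   (scalar trace of the moment statistic), `k`, `method = "mv_random"`.
#' @export
multivariate_random_effects <- function(estimates, covariances,
                                        diagonal = FALSE) {
  stopifnot(is.list(estimates), is.list(covariances))
  k <- length(estimates)
  assert_that(k >= 2 && length(covariances) == k,
              "need k >= 2 studies with matching covariances")
  p <- length(estimates[[1]])
  assert_that(all(vapply(estimates, length, 1L) == p),
              "estimate vectors differ in dimension")
  assert_that(all(vapply(covariances, function(S)
    all(dim(S) == c(p, p)), TRUE)), "covariance dimensions mismatch")
  y <- lapply(estimates, as.numeric)
  S <- lapply(covariances, function(M) (M + t(M)) / 2)

  if (diagonal) {
    ## coordinatewise univariate DL for the diagonal of Psi
    psi_diag <- vapply(seq_len(p), function(j) {
      dersimonian_laird(vapply(y, `[`, 0, j),
                        sqrt(vapply(S, function(M) M[j, j], 0)))$tau2
    }, 0)
    Psi <- diag(psi_diag, p)
  } else {
    W <- lapply(S, solve)
    P <- Reduce(`+`, W)
    Pinv <- solve(P)
    mu_f <- drop(Pinv %*% Reduce(`+`, Map(function(Wi, yi) Wi %*% yi, W, y)))
    r <- lapply(y, function(yi) yi - mu_f)
    Wh <- lapply(W, mat_sqrt)
    Qmat <- Reduce(`+`, Map(function(Whi, ri)
      Whi %*% (ri %o% ri) %*% Whi, Wh, r))

    ## E[Q] = L0 + L(Psi), L linear; build L on a basis of symmetric matrices
    expectation <- function(Psi) {
      V <- Map(function(Si) Si + Psi, S)
      VarMu <- Pinv %*% Reduce(`+`, Map(function(Wi, Vi)
        Wi %*% Vi %*% Wi, W, V)) %*% Pinv
      Reduce(`+`, Map(function(Whi, Wi, Vi) {
        Eri <- Vi - Vi %*% Wi %*% Pinv - Pinv %*% Wi %*% Vi + VarMu
        Whi %*% Eri %*% Whi
      }, Wh, W, V))
    }
    L0 <- expectation(matrix(0, p, p))
    ## basis of symmetric p x p matrices
    basis <- list()
    for (a in seq_len(p)) for (b in a:p) {
      B <- matrix(0, p, p); B[a, b] <- B[b, a] <- 1
      basis[[length(basis) + 1]] <- B
    }
    vech_idx <- which(lower.tri(diag(p), diag = TRUE))
    Lmat <- vapply(basis, function(B)
      (expectation(B) - L0)[vech_idx], numeric(length(vech_idx)))
    rhs <- (Qmat - L0)[vech_idx]
    theta <- solve(Lmat, rhs)
    Psi <- matrix(0, p, p)
    for (i in seq_along(basis)) Psi <- Psi + theta[i] * basis[[i]]
    Psi <- psd_clip(Psi)
  }

  Wr <- lapply(S, function(Si) solve(Si + Psi))
  Pr <- Reduce(`+`, Wr)
  Vpool <- solve(Pr)
  mu <- drop(Vpool %*% Reduce(`+`, Map(function(Wi, yi) Wi %*% yi, Wr, y)))
  ## scalar heterogeneity summary: trace of the fixed-effect moment statistic
  Wf <- lapply(S, solve)
  Pf <- solve(Reduce(`+`, Wf))
  mu_f2 <- drop(Pf %*% Reduce(`+`, Map(function(Wi, yi) Wi %*% yi, Wf, y)))
  Qtr <- sum(vapply(seq_len(k), function(i) {
    ri <- y[[i]] - mu_f2
    drop(t(ri) %*% Wf[[i]] %*% ri)
  }, 0))
  out <- list(estimate = mu, vcov = Vpool, psi = Psi, Q = Qtr, k = k,
              method = "mv_random")
  class(out) <- "mv_meta_result"
  out
}

#' @export
print.mv_meta_result <- function(x, ...) {
  cat(sprintf("Multivariate random-effects meta-analysis (k = %d, p = %d)\n",
              x$k, length(x$estimate)))
  cat("pooled:", format(x$estimate, digits = 4), "\n")
  invisible(x)
}
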