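---
title: "Nonlinear Mendelian randomization of kidney function: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear Mendelian randomization of kidney function: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Observationally, creatinine-based estimated glomerular filtration rate
(eGFR) has a U-shaped association with coronary heart disease and stroke:
risk is elevated both at low eGFR (kidney dysfunction) and at very high
eGFR. The high end is suspect — serum creatinine reflects muscle mass and
transient hyperfiltration as well as filtration, so an apparently
"supranormal" eGFR can mark frailty or metabolic disturbance rather than
healthy kidneys. `kidneymr` implements the two complementary analyses that
disentangle this:

1. **Observational arm.** Stratified Cox proportional-hazards models
   (optionally Prentice-weighted for case-cohort designs) with
   fractional-polynomial dose-response curves in eGFR, pooled across
   studies by multivariate random-effects meta-analysis and anchored at a
   reference of 90 mL·min⁻¹·1.73 m⁻².
2. **Nonlinear Mendelian randomization (MR) arm.** A weighted genetic risk
   score (GRS) for eGFR is used as an instrumental variable within strata
   of the exposure distribution, giving a localized average causal effect
   (LACE) per stratum by the ratio method, pooled across studies by
   fixed-effect meta-analysis and assembled into a piecewise-linear causal
   curve, also anchored at 90.

Because the consortium data behind such analyses are not redistributable,
the package ships a calibrated multi-study cohort simulator so that every
stage is testable at desk scale against known truth.

# Models

## Kidney function

eGFR is computed with the 2009 CKD-EPI creatinine equation

$$\mathrm{eGFR} = 141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha}
 \cdot \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}}
 \cdot 1.018[\text{female}]$$

with $\kappa = 0.7/0.9$ and $\alpha = -0.329/-0.411$ for women/men.
Creatinine from assays not standardized to isotope-dilution mass
spectrometry is first multiplied by 0.95. The race coefficient is omitted
because the supported analyses are restricted to single-ancestry cohorts.
Eligibility follows six criteria (age 30–80, recorded core fields,
eGFR < 300, no CVD/diabetes history, complete risk factors, ≥ 1 year of
follow-up), with each exclusion attributed to the first failing criterion.
The age window is treated as inclusive at both ends and the follow-up rule
as `time >= 1.0` exactly; neither boundary convention is settled usage, so
both are package decisions, recorded here.

## Genetic risk score

The score is $s_i = \sum_j w_j g_{ij}$ over retained variants, where
$g_{ij}$ is the effect-allele dosage and $w_j$ the conditional per-allele
weight. Variants flagged for ancestry heterogeneity, risk-factor
association, or missingness in any contributing study are excluded before
scoring; a variant with several flags is removed once but tallied under
each flag. The score is characterized two ways, because the two published
summaries are different quantities: `r2` is the *incremental* R² over a
covariate-only linear model of eGFR, while `sd_slope` is the *univariable*
standardized slope (SD eGFR per SD score; equal to the correlation, so
`sd_slope^2 == r2` in the univariable case). An `association_scan` checks
the score against other traits (linear or logistic per trait), with
Bonferroni flags across the scanned traits — the multiplicity rule is a
package decision stated in the output metadata.

## Observational dose-response

Cox models are stratified by sex and study center and use Breslow tie
handling (ties are rare on a continuous time scale; Breslow is also the
convention that is simplest to verify against a written-out partial
likelihood, which the test suite does). For case-cohort designs the
Prentice pseudolikelihood is used: subcohort members are at risk
throughout, non-subcohort cases enter the risk set only just before their
own failure, and the variance is the sandwich estimate clustered on
participant. This is implemented in the counting-process representation
with an entry offset smaller than the smallest gap between distinct event
times.

Nonlinearity is modelled with fractional polynomials of eGFR/10 (the
rescaling keeps powers like $x^3$ and $x^{-2}$ numerically tame; curves
are reported back on the eGFR scale). Degree-2 models cover the 36
unordered power pairs from $\{-2,-1,-0.5,0,0.5,1,2,3\}$ (a repeated power
$p$ contributes $x^p$ and $x^p\ln x$; power 0 is $\ln x$). Model selection
is a closed test on the partial-likelihood deviance with a 3.84 threshold
(one degree of freedom at 5%): FP2 is kept only if it beats the best FP1
by at least 3.84, and FP1 only if it beats the linear model by the same
margin. The methodology leaves the degree cap and selection rule open;
this choice prefers parsimony and is deterministic given the data.

Study-specific FP coefficient vectors are pooled by multivariate
random-effects meta-analysis. The between-study covariance uses a matrix
method of moments built on the statistic
$Q = \sum_i W_i^{1/2} r_i r_i' W_i^{1/2}$ (fixed-effect weights
$W_i = S_i^{-1}$, GLS residuals $r_i$), solved from $E[Q] = Q$ and
truncated to the positive-semidefinite cone by eigenvalue clipping. In one
dimension this reduces *exactly* to DerSimonian–Laird, which pins the
estimator to the univariate convention; the reduction is exercised in the
tests. Power selection is done once on the combined data (centers as
strata), then each study is refit with the selected powers so that
coefficients are commensurable across studies.

## Nonlinear MR

Stratification comes in two flavours:

- **Residual method** (primary): per study, eGFR is regressed on the
  centered score; the residual
  $\tilde{x}_i = x_i - \hat\beta (s_i - \bar s)$ keeps the eGFR scale and
  is independent of the score under a homogeneous linear score-exposure
  effect, so strata defined by $\tilde x$ do not re-introduce collider
  bias. Strata are the 12 five-unit bins from 45 to 105 plus the two open
  tails — 14 in all. A non-positive fitted slope is a hard error: it can
  only arise from an orientation bug upstream.
- **Doubly-ranked method** (sensitivity): sort by score, form consecutive
  pre-strata of size equal to the number of strata, rank each pre-stratum
  by exposure, and send the q-th ranked member to stratum q; remainders
  follow the same rank rule and ties are broken by stable input order.

Within each stratum, the LACE is the ratio estimate
$\hat\theta = \hat\beta_{YG}/\hat\beta_{XG}$: the instrument-outcome
coefficient from logistic regression of incident case status on the score
(adjusted for age, age², sex, center and 10 principal components) over the
instrument-exposure coefficient from the analogous linear regression. The
denominator is estimated *within stratum*; a configuration switch enables
a pooled denominator, since published descriptions leave this open. The
standard error is the first-order delta method
$SE(\hat\beta_{YG})/|\hat\beta_{XG}|$; a second-order correction is
available behind a flag and can be checked against the bootstrap. Ratios
with first-stage $|t| < 2$ carry a weak-instrument flag. Strata need at
least 100 participants and 10 events (configurable floors). The odds ratio
per 5 units *lower* eGFR is $\exp(-5\hat\theta)$; a directional unit test
pins the sign convention.

Stratum estimates are pooled across studies by inverse-variance
fixed-effect meta-analysis. The causal curve assigns each pooled stratum a
segment spanning the central 90% of its members' observed eGFR, abutted to
neighbours at midpoints (how published curves place strata on the x-axis
is not stated; this choice uses only observed exposure support), gives the
segment the stratum's LACE as slope, and integrates outward from the
reference 90 — so the curve is exactly zero at 90 by construction, in
every resampling draw. Pointwise 95% intervals come from B = 1000
independent normal resamples of the stratum LACEs (fixed-effect pooled
estimates carry no cross-stratum covariance, so independent draws are
appropriate); B < 100 is rejected as unstable. Cochran's Q across strata
and an inverse-variance meta-regression of LACE on mean stratum exposure
summarize heterogeneity and trend.

# The synthetic cohort generator

The generator emulates the features the estimators rely on, with defaults
fixed once from the study conditions and ordinary epidemiological
magnitudes:

- **Genotypes**: independent binomial dosages at Hardy–Weinberg
  proportions (218 variants by default). No linkage disequilibrium is
  simulated: the score, not the variants, is the instrument, so LD does
  not enter the estimator contracts.
- **Score calibration**: raw weights are rescaled so the population score
  variance is `mean(target_grs_r2) * egfr_sd^2`; per-study exposure
  variance is then `var(score)/target_r2`, and the Gaussian noise variance
  is solved analytically (never rescaled post hoc), making the target R² a
  population property. Per-study targets default to 2.0%, 2.2% and 3.2%.
- **Exposure**: eGFR = 90 + score + confounder effect + noise, anchored at
  `egfr_sd = 19`. That width puts roughly 5–6% of the cohort below 60,
  matching the low-eGFR prevalence of broad-age multi-study consortia.
  Creatinine is emitted by inverting the CKD-EPI equation (study 1 is
  marked non-IDMS-standardized, so the 0.95 calibration path is exercised
  end to end).
- **Confounder**: a standard-normal "muscle-mass/hyperfiltration" variable
  raising both eGFR (+6 units/SD) and log hazard (+0.3/SD). This is what
  produces the observational U-shape at high creatinine-based eGFR while
  leaving the causal curve flat there — the package's own tests assert
  exactly that contrast.
- **Events**: exponential times with rate
  `baseline_hazard * exp(causal(egfr) + 0.3 * U)` and administrative
  censoring, the simplest proportional-hazards-faithful model (a Weibull
  shape is a config extension). Defaults `baseline_hazard = 0.01`/year and
  15 years of follow-up describe a long-running cohort and give the
  low-eGFR strata enough events for stratum-level inference; cumulative
  incidence (~14%) is at the high end of consortium experience.
- **Causal curve**: piecewise linear in eGFR, value 0 at 90; the default
  is slope −0.028 per unit below a changepoint at 75 and 0 above —
  i.e. exp(5 × 0.028) ≈ 1.15 per 5 units lower eGFR below the
  changepoint, and no effect above it.
- **Case-cohort**: optional Bernoulli subcohort with all cases retained.

What the generator does **not** emulate: LD and imputation noise,
non-Gaussian eGFR tails, competing risks, covariate-dependent hazards
(age, sex and risk factors are adjustment noise by design), study-level
follow-up heterogeneity, or non-European allele frequencies. Passing
tests therefore demonstrate estimator correctness under the assumed
structure, not robustness to violations of it.

# Numerical choices and problem sizes

- Exposure floors (eGFR clipped at 2, HDL at 0.3, BMI at 14) affect a
  vanishing tail and keep log/negative-power transforms defined.
- The piecewise curve is evaluated by cumulative integration over a finite
  hull of the knots, which is well conditioned and vectorized.
- Determinism: every stochastic function takes a seed; a scenario config
  (including its seed) reproduces cohorts byte-for-byte, and the pipeline
  is deterministic given its run config.
- The validation suites run at reduced problem sizes chosen to keep the
  whole suite in minutes while retaining power: parameter recovery uses
  the full 3 × 50,000 default with 30 variants over 100 replicates; null
  calibration uses 500 replicates of a single 6,000-participant study;
  score-calibration checks use n = 100,000.

# Known limitations

- The first-order delta-method SE ignores first-stage uncertainty; with
  the default score strength the neglected term is second order, and the
  optional correction quantifies it.
- Fixed-effect pooling of stratum LACEs (the convention for this design)
  understates between-study heterogeneity if targets differ materially
  across studies; the per-stratum Q statistic is reported for diagnosis.
- The residual method's independence property is exact only under a
  homogeneous linear score-exposure effect; the doubly-ranked method is
  provided precisely because it does not need that assumption, and the
  suite checks that the two agree on simulated data satisfying it.
- Logistic regression of incident case status is the outcome model for
  the MR arm (the convention for cohort MR of binary incident outcomes;
  published per-5-unit relative risks do not state a likelihood). It
  discards time-to-event information; with event rates in the simulated
  range the efficiency loss is modest. Continuous outcomes use linear
  regression, where the ratio estimate is algebraically two-stage least
  squares.
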