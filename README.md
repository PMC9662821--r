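# kidneymr

Nonlinear Mendelian randomization and observational dose-response analysis
of kidney function (creatinine-based eGFR) versus incident cardiovascular
outcomes, for biostatisticians and genetic epidemiologists working with
multi-study cohort data.

## What it does

Observationally, eGFR shows a U-shaped association with coronary heart
disease and stroke; part of the high-eGFR arm is an artifact of serum
creatinine (muscle mass, hyperfiltration). `kidneymr` implements both sides
of the comparison that separates cause from artifact:

- **Kidney metrics** — the 2009 CKD-EPI creatinine equation
  `141 · min(Scr/κ,1)^α · max(Scr/κ,1)^(−1.209) · 0.993^age · 1.018[female]`,
  IDMS calibration (×0.95 for non-standardized assays), and the six-criterion
  cohort eligibility filter with first-failure exclusion tallies.
- **Genetic risk score** — weighted allele-dosage score `s_i = Σ_j w_j g_ij`
  with flag-based variant exclusions, incremental variance explained, the
  univariable standardized slope, and a trait-association scan.
- **Observational arm** — sex/center-stratified Cox models (Breslow ties),
  Prentice-weighted pseudolikelihood for case-cohort designs with robust
  variance, fractional-polynomial dose-response curves (powers from
  {−2,−1,−0.5,0,0.5,1,2,3}, closed-test selection), pooled across studies by
  multivariate random-effects meta-analysis, anchored at eGFR 90.
- **Nonlinear MR arm** — residual-method stratification (14 strata: five-unit
  bins 45–105 plus open tails) or non-parametric doubly-ranked
  stratification; per-stratum localized average causal effects (LACE) by the
  ratio method `θ = β_YG / β_XG` with delta-method SEs; fixed-effect pooling
  across studies; a piecewise-linear causal curve with resampled pointwise
  CIs, exactly zero at the reference 90; heterogeneity and trend tests. The
  odds ratio per 5 units lower eGFR is `exp(−5θ)`.
- **Meta-analysis primitives** — inverse-variance fixed-effect,
  DerSimonian–Laird, and a multivariate method-of-moments random-effects
  estimator that reduces exactly to DerSimonian–Laird in one dimension.
- **Synthetic cohorts** — a calibrated multi-study generator (polygenic score
  explaining a target share of eGFR variance, configurable piecewise-linear
  causal curve, a confounder inducing the observational U-shape, exponential
  event times with censoring, optional case-cohort subsampling) so that every
  stage is testable against known truth without access restrictions.

See `vignettes/kidneymr-methods.Rmd` for the models, assumptions, defaults
and design decisions.

## Worked example

Simulate a three-study cohort, write/read the TSV bundle, and run the MR arm:

```r
library(kidneymr)

cfg <- scenario_config(n_per_study = 20000, n_studies = 3,
                       n_variants = 50, seed = 42)
cohort <- simulate_cohort(cfg)
paths  <- write_cohort(cohort, "demo_cohort")
report <- run_pipeline(run_config(paths = paths, arm = "mr",
                                  B = 500, seed = 42))
print(report)
#> Pipeline report
#>   eligibility: 54544 of 60000 retained
#>   variants: 50 of 50 retained
#>   score R^2 by study: S1=0.022, S2=0.023, S3=0.036
#>   MR: 14 pooled strata; curve anchored at 90
```

The pooled stratum table (`report$mr$pooled`) carries, per stratum, the
pooled LACE (log-odds per unit eGFR), its SE, and the odds ratio per 5 units
lower eGFR with 95% CI. With the default generator truth (causal slope
−0.028 per unit below eGFR 75, zero above), the low strata show elevated
odds ratios and the high strata sit at the null:

```r
report$mr$pooled[c(1, 5, 14),
                 c("stratum", "n", "events", "per5_or",
                   "per5_ci_low", "per5_ci_high")]
#>    stratum     n events per5_or per5_ci_low per5_ci_high
#> 1      <45   502    146   1.615       1.135         2.30
#> 5  [60,65)  1952    326   1.305       1.061         1.60
#> 14   >=105 11761   1795   0.966       0.892         1.05
```

Pooling the strata below 60 gives the headline-style regional estimate:

```r
below60 <- subset(report$mr$pooled,
                  stratum %in% c("<45", "[45,50)", "[50,55)", "[55,60)"))
fe <- fixed_effect(below60$lace, below60$se)
cat(sprintf("OR per 5 units lower eGFR below 60: %.2f (95%% CI %.2f-%.2f)\n",
            exp(-5 * fe$estimate),
            exp(-5 * fe$estimate - 1.96 * 5 * fe$se),
            exp(-5 * fe$estimate + 1.96 * 5 * fe$se)))
#> OR per 5 units lower eGFR below 60: 1.20 (95% CI 1.03-1.39)
```

that is, at this desk-scale sample size, each 5-unit decrement of
genetically predicted eGFR below 60 is associated with ~20% higher odds of
the outcome, while strata above the changepoint are compatible with no
effect — the qualitative signature the method is designed to recover.
`report$mr$curve` holds the piecewise-linear curve with resampled CIs
(`plot(report$mr$curve)` draws it); `arm = "both"` adds the observational
fractional-polynomial curve, which — unlike the MR curve — turns upward
above the reference because of the simulated creatinine artifact.

A thin command-line wrapper is installed at `inst/cli/run_pipeline.R`
(subcommands `simulate` and `run`).

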