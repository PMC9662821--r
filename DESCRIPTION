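Package: kidneymr
Title: Nonlinear Mendelian Randomization of Kidney Function and Cardiovascular Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the dose-response relationship between
    creatinine-based estimated glomerular filtration rate (eGFR) and incident
    cardiovascular outcomes in multi-study cohorts, by both observational
    survival analysis and nonlinear Mendelian randomization. Implements the
    2009 CKD-EPI creatinine equation and cohort eligibility filtering, weighted
    genetic risk scores with variant exclusion accounting, stratified and
    Prentice-weighted (case-cohort) Cox models with fractional-polynomial
    dose-response curves, residual-method and doubly-ranked stratification
    with ratio-method localized average causal effect (LACE) estimation,
    fixed-effect and (multivariate) DerSimonian-Laird meta-analysis, and a
    calibrated multi-study cohort simulator for validating every stage at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse,
    ggplot2
Config/testthat/edition: 3
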