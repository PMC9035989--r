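Package: linpoppk
Title: Population Pharmacokinetics and Trough-Targeted Dosing of Linezolid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects (FOCE-I) estimation of a one-compartment
    intravenous-infusion model for linezolid in critically ill patients, with a
    creatinine-clearance covariate on clearance, MAP Bayesian individual exposure
    estimation, an exposure-toxicity logistic model for myelosuppression with its
    50%-probability trough threshold, a trough-to-AUC surrogate regression, the
    derived 2.6-7.8 mg/L therapeutic trough window, model diagnostics (CWRES,
    shrinkage, nonparametric bootstrap, prediction- and variability-corrected
    visual predictive checks), Monte Carlo probability-of-target-attainment
    dosing simulation across renal-function strata, and a synthetic-cohort
    generator emulating sparse trough-dominant therapeutic drug monitoring data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
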