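Package: pssprev
Title: Prevalence Estimation from Two-Phase Surveys with Informative
    Non-Response via Propensity Score Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates three-category cognitive-status prevalence (normal,
    mild cognitive impairment, dementia) from two-phase prevalence surveys in
    which many phase-II participants fail to complete the diagnostic battery
    and the resulting missingness is informative (missing not at random).
    Fits a logistic non-response propensity model with backward-AIC variable
    selection, partitions phase-II subjects into equal-size propensity-score
    strata, estimates stratum prevalence by simple (binomial) estimation,
    ordinal-regression fill-in, and ordinal-regression multiple imputation
    pooled by Rubin's rules, and combines strata into phase-II and overall
    cohort estimates. Includes a configurable synthetic two-phase survey
    generator with a latent proportional-odds disease process and a logistic
    non-response mechanism for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
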