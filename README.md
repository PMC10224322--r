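# pssprev

Prevalence estimation from two-phase surveys with informative non-response,
via propensity-score stratification.

## The problem

Dementia prevalence surveys typically run in two phases: a cheap cognitive
screen (MMSE, MoCA, activities-of-daily-living scales) labels part of the
cohort "normal", and the remainder receives a full neuropsychological
diagnostic battery. Many phase-II participants — disproportionately the
frailest and most cognitively impaired — fail to complete the battery, so
their three-level diagnosis (normal / MCI / dementia) is missing **not at
random** (MNAR): the probability of missingness depends on the very outcome
being measured. Dropping these non-responders (complete-case analysis)
underestimates prevalence.

`pssprev` is for epidemiologists and biostatisticians analysing such
surveys, and for methodologists studying non-response corrections. It
implements:

1. **Non-response propensity model.** A logistic regression of the
   phase-II non-response indicator on observed covariates
   (age, education, PADL, IADL, MMSE, MoCA), with backward elimination
   under AIC:
   `logit P(nonresponse | x) = alpha + x'gamma`.
   A rank-sum comparison of the fitted scores between responders and
   non-responders, and a covariate balance table (standardized mean
   differences), diagnose whether the missingness is informative.
2. **Quantile stratification.** Phase-II subjects are cut into K = 5
   equal-size strata by the empirical quintiles of the propensity score.
   Within a stratum, responders and non-responders are approximately
   comparable, so the missingness is approximately MAR (Rosenbaum–Rubin
   subclassification applied to non-response).
3. **Stratum-level estimators.**
   - **SE** (simple estimation): category share among the stratum's
     responders, binomial variance p(1−p)/m.
   - **RE** (regression estimation): proportional-odds logistic model
     `logit P(Y <= k | x) = zeta_k − x'beta` fitted on responders
     (backward-AIC), non-responders filled in with their predicted
     category probabilities; SD by stratified bootstrap.
   - **REMI** (regression estimation with multiple imputation): m proper
     imputations drawn from the model's approximate posterior, pooled by
     Rubin's rules (total variance = within + (1 + 1/m) x between).
4. **Pooling and dilution.** Stratum estimates are combined by a
   size-weighted average into a phase-II estimate, then diluted to the
   whole cohort by n_II/(n_I + n_II), treating phase-I screen-negatives as
   disease-free.

Because real survey records of this kind are restricted, the package ships
a configurable **synthetic two-phase survey generator** (correlated
covariates, latent proportional-odds disease status, imperfect phase-I
screen, logistic MNAR non-response) whose defaults are calibrated to the
published characteristics of a large veteran cohort; every estimator is
validated against it.

## Worked example

```r
library(pssprev)
cfg <- sim_config(n_total = 4000, seed = 42)   # calibrated defaults
sv  <- generate_survey(cfg)
fit <- pss_estimate(sv, k = 5, B = 100, m = 10, seed = 42)
print(fit)
```

```
Synthetic two-phase survey: 4000 subjects
  phase I normal: 1878  phase II: 2122
  responders: 1562  non-responders: 560
PSS prevalence analysis: k = 5 strata, 2122 phase-II + 1878 phase-I subjects
  RE    dementia overall: 11.05% (sd 0.53)
  REMI  dementia overall: 11.19% (sd 0.55)
  SE    dementia overall: 11.01% (sd 0.54)
```

The three stratified estimators agree to within 0.2 percentage points. The
naive complete-case estimate on the same dataset is

```r
cc <- complete_case_prevalence(sv)
cc$point[cc$category == "dementia"]
#> 8.98
```

— more than two points below the corrected estimates, the downward bias
that informative non-response produces. The fitted propensity model shows
where the missingness comes from (worse MoCA, higher age and dependency):

```
Non-response propensity model (logistic, backward-AIC)
  n = 2122  AIC = 2401.2
  logit(PS) = -3.775 +0.038*age +0.035*padl +0.022*mmse -0.068*moca
```

Phase-II-scope estimates, per-stratum tables, the balance table and the
stratum assignment are all in the returned object (`fit$phase2_estimates`,
`fit$stratum_estimates`, `fit$stratum_summary`, ...). `run_pipeline()`
wraps the whole analysis (validation included) and writes a report
directory; `inst/scripts/pss_pipeline.R` exposes it on the command line
with `simulate` / `estimate` / `validate` subcommands.

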