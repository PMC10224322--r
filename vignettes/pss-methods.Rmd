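---
title: "Methods: propensity-score stratification for prevalence estimation under informative non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-score stratification for prevalence estimation under informative non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssprev)
```

## The estimation problem

A two-phase prevalence survey screens a cohort of size $n$ with cheap
cognitive and functional instruments; $n_I$ screen-negatives are labelled
normal and only $n_{II} = n - n_I$ subjects receive the full diagnostic
battery in phase II. A substantial fraction of phase-II subjects cannot
complete the battery; their three-level diagnosis
$Y \in \{\text{normal}, \text{MCI}, \text{dementia}\}$ is missing, and the
probability of missingness increases with impairment — the mechanism is
MNAR. The complete-case prevalence (diagnosed cases over diagnosed
subjects) is then biased downward.

The package's correction treats non-response itself as the "treatment" in
a Rosenbaum–Rubin subclassification. Let $R$ indicate non-response and $x$
the observed covariates (age, years of education, PADL, IADL, MMSE, MoCA).
The non-response propensity score

$$e(x) = P(R = 1 \mid x) = \operatorname{logit}^{-1}(\alpha + x'\gamma)$$

is estimated by logistic regression on the phase-II subjects. Partitioning
phase II into $K$ equal-size strata by the empirical quantiles of
$\hat e(x)$ makes responders and non-responders approximately exchangeable
within a stratum, so within-stratum missingness can be treated as MAR.
Stratum prevalences are estimated by SE, RE or REMI (below), pooled by a
size-weighted average, and diluted to the whole cohort by
$n_{II}/(n_I + n_{II})$ under the design assumption that screen-negatives
are disease-free.

If the missingness were ignorable given nothing (MCAR) the propensity
model would have no signal: backward-AIC selection then retains few or no
covariates and the rank-sum comparison of scores between responders and
non-responders is null-calibrated. A significant score separation together
with outcome-related covariates in the selected model is the package's
working diagnostic of informative missingness.

## Estimators

Write $m_k$ for the responders and $n_k$ for all subjects of stratum $k$,
and $p$ for a category share (in percent).

**SE.** $\hat p_k$ = category share among the $m_k$ responders;
$\operatorname{sd} = \sqrt{\hat p_k(1-\hat p_k)/m_k}$. Unbiased given
within-stratum MAR; uses no covariate information.

**RE.** A proportional-odds model
$\operatorname{logit} P(Y \le k \mid x) = \zeta_k - x'\beta$ is fitted on
the stratum's responders by maximum likelihood (`MASS::polr`), with the
same backward-AIC elimination as the propensity model, so the selected
covariates may differ between strata. The stratum estimate adds the
observed responder counts and the predicted category probabilities of each
non-responder, divided by $n_k$. When the stratum has no non-responders the
fill-in sum is empty and RE equals SE exactly — this identity pins the
convention that RE predicts for non-responders only rather than refitting
everyone.

The RE sampling variance has no convenient closed form once covariates are
selected per stratum, so the package uses a stratified bootstrap:
responders are resampled with replacement, the selected model (selection
frozen) is refitted, the fixed non-responders re-predicted, and the SD of
the bootstrap points reported. $B = 200$ by default; $B = 0$ skips the
bootstrap when only points are needed (e.g. in replicate studies).

**REMI.** Multiple imputation is combined with simple estimation: for each
of $m$ imputations a parameter vector is drawn from the large-sample
posterior approximation $N(\hat\theta, \widehat{\operatorname{cov}})$ of
the stratum's ordinal fit, each non-responder's diagnosis is sampled from
the implied category probabilities, and the completed-stratum share and its
binomial variance are recorded. Rubin's rules pool the $m$ estimates:
point = mean; total variance = mean within-imputation variance
$+ (1 + 1/m)\times$ between-imputation variance. Default $m = 20$; the
normal-at-the-MLE approximation is the standard large-sample Bayesian
choice and keeps imputation cheap enough for replicate studies. Drawn
cutpoints are sorted if a draw inverts them (rare, small strata only).

**Degenerate strata.** If a stratum's responders show only two outcome
categories the ordinal model reduces to a binomial logistic regression with
one cutpoint (the absent category gets probability zero; `MASS::polr`
itself requires three levels). A single observed category makes RE/REMI
fall back to SE with a logged flag; a stratum with *no* responders makes
the pipeline reduce $K$ by one and re-stratify, with a warning.

## Pooling, dilution, intervals

The phase-II estimate is $\sum_k w_k \hat p_k$ with $w_k = n_k/n_{II}$ and
variance $\sum_k w_k^2 \sigma_k^2$ (strata are independent). Dilution to
the overall cohort multiplies disease-category points and SDs by
$n_{II}/(n_I + n_{II})$; the normal category gains the phase-I mass so the
three categories still sum to 100%. Phase-I subjects are treated as fixed
and disease-free — screen false negatives are ignored by the estimator,
exactly as two-phase surveys conventionally assume; the generator *does*
produce such false negatives, so their (small) effect is visible in
validation as a gap between the estimators' target and the cohort's true
latent prevalence. All intervals are normal approximations
$\text{point} \pm 1.96\,\text{sd}$, clipped to $[0, 100]$.

## Design choices in genuinely open territory

* **Stepwise procedure.** "Stepwise with AIC" admits several algorithms;
  the package uses backward elimination from the full candidate set,
  removing the term whose deletion lowers AIC most until no deletion
  lowers it. Backward-from-full is deterministic, order-invariant, and
  treats the candidate set symmetrically. Ties (within floating-point
  equality) resolve to the earliest candidate, which is fixed by the
  canonical covariate order.
* **Balance-table test.** Responders and non-responders are independent
  groups, so the rank-based test is the Wilcoxon rank-sum (Mann–Whitney)
  test, not the signed-rank test (which requires paired data). The t test
  is used only when both groups pass a Shapiro–Wilk pre-check at
  $\alpha = 0.05$ (each group subsampled to at most 5000 values, the
  test's implementation cap); `test = "t"` or `"wilcoxon"` overrides.
* **SMD.** $|\mu_1 - \mu_0| / \sqrt{(s_1^2 + s_0^2)/2}$, the pooled-SD
  convention; zero pooled SD is flagged and reported as SMD 0.
* **Stratification.** Rank-based equal-count blocks (sizes differ by at
  most one, larger blocks first; ties broken by stable input order) rather
  than value-interpolated quantile cuts: this guarantees the equal-size
  contract (e.g. 4445 subjects split 889 x 5) even with tied scores.
* **Candidate covariates.** Default
  $\{$age, education, PADL, IADL, MMSE, MoCA$\}$ — the demographic and
  screening variables available for responders and non-responders alike.

## The synthetic survey generator

Real diagnostic records of this kind are restricted, so validation runs on
a generator that emulates the statistical structure the analysis assumes,
with all constants in `inst/extdata/default_config.yaml`:

* **Covariates** are multivariate normal with the responder-table means
  and SDs of a large veteran cohort (age 82.9 ± 3.7, education 7.5 ± 4.6,
  PADL 12.3 ± 5.0, IADL 15.3 ± 8.7, MMSE 24.9 ± 5.2, MoCA 21.5 ± 5.6);
  only the marginal moments are published, so the correlation structure is
  a modelling choice: 0.5 between MMSE and MoCA, 0.4 between PADL and
  IADL, 0 elsewhere. MMSE and MoCA are clipped to the instrument range
  [0, 30] (`clip_scores = FALSE` disables it; clipping truncates the upper
  tail and lowers those two sample means by about 0.45 and 0.15 points —
  an accepted distortion, since the clipped range is what real scores
  obey). Scores stay continuous; `round_scores = TRUE` rounds to integers.
* **Latent status** follows a proportional-odds model on the covariates
  (impairment loads negatively on MMSE/MoCA, positively on age and
  dependency scores) with cutpoints (−0.53, 1.74).
* **Phase-I screen**: impaired subjects reach phase II with sensitivity
  0.92; truly normal subjects are screened out with specificity 0.83.
  The survey never published its screen's operating characteristics, so
  these are calibration choices, chosen jointly with the cutpoints to
  reproduce the published phase flow (below). Missed impaired subjects are
  labelled normal — the design's false negatives.
* **Non-response** is logistic in the covariates plus
  `nonresp_status_boost` x latent status level (0/1/2). The boost is the
  MNAR knob: 0 makes missingness ignorable given covariates; the default
  0.20 makes the unobserved diagnosis itself raise non-response.

Default calibration targets, all taken from the published survey: phase-II
fraction 4445/8246 ≈ 53.9%, phase-II non-response 1170/4445 ≈ 26.3%,
responder mix 589/1979/707 (normal/MCI/dementia), responder-vs-non-
responder SMDs ≈ 0.27 (MoCA), 0.15 (MMSE), 0.14 (PADL), 0.06 (IADL), and
an overall dementia prevalence near 12%. The boost value is pinned by the
published gap between the phase-II complete-case share (21.6%) and the
corrected estimate (22.7%): most of the covariate imbalance must therefore
come through the covariate path, not the status path. At n = 300,000 the
frozen defaults achieve phase-II 53.6%, non-response 26.6%, mix
17.8/61.1/21.0%, SMDs 0.27/0.13/0.15/0.06, overall dementia 12.4%.

What the generator does **not** emulate — so what passing tests cannot
show: clustering by community or city (single homogeneous population), any
longitudinal structure, item-level missingness within the battery,
diagnostic misclassification among responders, and integer-valued scores
(off by default). Conclusions about those features require real data.

## Numerical and reproducibility notes

* One master seed drives everything; per-stage substreams (generator,
  propensity fit, bootstrap/imputation) are derived with fixed offsets so
  that, e.g., changing $m$ does not perturb the generated dataset.
* `polr` is fitted with `Hess = TRUE`; non-convergence, singular Hessians
  or non-PSD variance matrices are caught and either fall back to SE
  (estimation) or raise an informative error (imputation), advising fewer
  strata.
* Quasi-complete separation in the propensity model is detected from the
  fitted-probability warning and reported with the most plausible
  separating covariate.
* Presentation rounding in report CSVs is half-up at 2 decimals; all
  internal arithmetic is full precision. (Half-up reproduces conventional
  table formatting; base R's round-half-even does not.)

## Validation problem sizes

The test suite exercises the pipeline at the survey's own scale where the
check is cheap (coefficient recovery at $n_{II} = 4445$; bias-direction
replicates at $n = 8246$) and at reduced scale where many replicates are
needed: cross-method consistency on 50 replicates at $n = 2000$ with
$B = 0$ and $m = 10$ (method spread uses points only, so the bootstrap SD
is not needed), MCAR equivalence on 30 replicates at $n = 2000$, and
interval coverage on 100 replicates at $n = 1000$ with $B = 60$, $m = 10$.
These sizes are the package's validation design: large enough for the
Monte-Carlo bands asserted in the tests, small enough to run routinely.

## Known limitations

* Within-stratum MNAR is reduced, not eliminated: with a positive status
  boost a small residual downward bias remains in all three estimators
  (the score can only balance what covariates carry). Coverage checks in
  the test suite quantify this at the default calibration.
* The RE bootstrap resamples responders only, treating the non-responder
  covariate set as fixed; it ignores selection uncertainty (the chosen
  covariates are frozen per bootstrap draw).
* The dilution step inherits the design's screen-negatives-are-normal
  assumption; sensitivity of the overall estimate to screen false
  negatives is outside the estimators' scope (the generator can quantify
  it via `truth`).
* Proportional odds is assumed, not tested, within strata; strata are
  small enough that formal PO tests would be underpowered anyway.
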