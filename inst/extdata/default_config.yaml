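# Calibration constants of the default synthetic two-phase survey.
# Covariate moments follow the responder column of a large veteran cohort's
# baseline table; screen operating characteristics, latent-status cutpoints
# and the non-response model are calibrated jointly so that at the default
# cohort size the phase-II fraction (~54%), the phase-II non-response
# fraction (~26%), the responder diagnosis mix (~18/60/22% normal/MCI/
# dementia) and the responder-vs-non-responder covariate imbalance
# (MoCA SMD ~0.27, MMSE ~0.15, PADL ~0.14, IADL ~0.06) match that survey.
n_total: 8246
cov_means:
  age: 82.89
  education: 7.52
  padl: 12.25
  iadl: 15.28
  mmse: 24.91
  moca: 21.48
cov_sds:
  age: 3.72
  education: 4.58
  padl: 5.01
  iadl: 8.74
  mmse: 5.16
  moca: 5.56
# order: age, education, padl, iadl, mmse, moca
cov_corr:
  - [1.0, 0.0, 0.0, 0.0, 0.0, 0.0]
  - [0.0, 1.0, 0.0, 0.0, 0.0, 0.0]
  - [0.0, 0.0, 1.0, 0.4, 0.0, 0.0]
  - [0.0, 0.0, 0.4, 1.0, 0.0, 0.0]
  - [0.0, 0.0, 0.0, 0.0, 1.0, 0.5]
  - [0.0, 0.0, 0.0, 0.0, 0.5, 1.0]
status_coefs:
  age: 0.05
  education: -0.02
  padl: 0.05
  iadl: 0.03
  mmse: -0.10
  moca: -0.15
status_cutpoints: [-0.53, 1.74]
screen_sensitivity: 0.92
screen_specificity: 0.83
nonresp_intercept: -1.58
nonresp_coefs:
  age: 0.01
  padl: 0.03
  iadl: 0.0
  mmse: 0.0
  moca: -0.045
nonresp_status_boost: 0.20
clip_scores: true
round_scores: false
seed: 20260924
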