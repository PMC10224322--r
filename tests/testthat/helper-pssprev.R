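# Shared fixtures, all built in code.

# A tiny hand-built participant table: n1 phase-I normals, then responders
# with the given diagnoses, then non-responders. Covariates are filled with
# reproducible noise unless supplied.
make_records <- function(n1 = 0, diagnoses = character(0), n_nonresp = 0,
                         covs = NULL, seed = 99) {
  n2 <- length(diagnoses) + n_nonresp
  n <- n1 + n2
  set.seed(seed)
  d <- data.frame(id = sprintf("T%05d", seq_len(n)))
  for (v in c("age", "education", "padl", "iadl", "mmse", "moca"))
    d[[v]] <- if (!is.null(covs) && v %in% names(covs)) covs[[v]]
              else round(rnorm(n, 20, 5), 3)
  d$phase <- rep(c("phase1_normal", "phase2"), c(n1, n2))
  d$responded <- c(rep(NA, n1), rep(TRUE, length(diagnoses)),
                   rep(FALSE, n_nonresp))
  d$diagnosis <- c(rep("normal", n1), diagnoses, rep("missing", n_nonresp))
  d
}

default_survey <- function(seed, n = NULL) {
  generate_survey(default_sim_config(), n_total = n, seed = seed)
}

# An intercept-only ordinal fit with fixed category probabilities and (by
# default) a zero variance matrix — used to exercise the imputation sampler
# in isolation.
fixed_prob_fit <- function(p, vcov_scale = 0) {
  stopifnot(abs(sum(p) - 1) < 1e-12)
  zeta <- c(zeta1 = stats::qlogis(p[1]), zeta2 = stats::qlogis(p[1] + p[2]))
  structure(list(levels = c("normal", "mci", "dementia"),
                 coefficients = stats::setNames(numeric(0), character(0)),
                 zeta = zeta,
                 vcov = diag(vcov_scale, 2),
                 aic = NA_real_, selected_covariates = character(0), n = 0L),
            class = "ordinal_fit")
}

# Phase-II-like covariate table drawn from the default config moments with
# clipping disabled (keeps linear-logistic truth exact).
draw_covariates <- function(n, seed) {
  cfg <- sim_config(clip_scores = FALSE)
  set.seed(seed)
  generate_covariates(cfg, n)
}

# The published non-response propensity model used as ground truth in
# recovery studies.
REF_PS <- list(intercept = -0.56,
               coefficients = c(moca = -0.08, mmse = 0.04,
                                padl = 0.03, iadl = -0.02))

ref_ps_model <- function() {
  structure(list(selected_covariates = names(REF_PS$coefficients),
                 intercept = REF_PS$intercept,
                 coefficients = REF_PS$coefficients,
                 aic = NA_real_, vcov = NULL, ps = numeric(0),
                 id = character(0), responded = logical(0), n = 0L),
            class = "ps_model_fit")
}
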