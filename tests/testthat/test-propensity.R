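test_that("intercept-only limit: flat response rate gives flat scores", {
  set.seed(20)
  n <- 1e4
  d <- data.frame(id = as.character(1:n), age = rnorm(n, 80, 4),
                  education = rnorm(n), padl = rnorm(n), iadl = rnorm(n),
                  mmse = rnorm(n), moca = rnorm(n, 20, 5),
                  phase = "phase2",
                  responded = runif(n) > 0.25)
  d$diagnosis <- ifelse(d$responded, "normal", "missing")
  fit <- fit_ps_model(d, candidate_covariates = "moca")
  expect_true(all(abs(fit$ps - 0.25) < 0.02))
})

test_that("mean propensity score equals the non-response fraction (MLE identity)", {
  sv <- default_survey(seed = 21, n = 3000)
  fit <- fit_ps_model(sv)
  d <- sv$records[sv$records$phase == "phase2", ]
  expect_lt(abs(mean(fit$ps) - mean(!d$responded)), 1e-6)
  expect_true(all(fit$ps > 0 & fit$ps < 1))
  # stored scores are reproduced exactly by predict_ps on the same subjects
  expect_equal(fit$ps, predict_ps(fit, d), tolerance = 1e-12)
})

test_that("published-model closed forms for predict_ps", {
  m <- ref_ps_model()
  at0 <- data.frame(moca = 0, mmse = 0, padl = 0, iadl = 0)
  expect_equal(predict_ps(m, at0), plogis(-0.56), tolerance = 1e-12)
  # one extra MoCA point multiplies the non-response odds by exp(-0.08)
  x1 <- data.frame(moca = 13, mmse = 24, padl = 12, iadl = 15)
  x2 <- transform(x1, moca = moca + 1)
  odds <- function(p) p / (1 - p)
  expect_equal(odds(predict_ps(m, x2)) / odds(predict_ps(m, x1)),
               exp(-0.08), tolerance = 1e-12)
  expect_error(predict_ps(m, data.frame(moca = 1, mmse = 1, padl = 1)),
               "iadl")
})

test_that("stepwise selection is invariant to row order", {
  sv <- default_survey(seed = 22, n = 2500)
  d <- sv$records[sv$records$phase == "phase2", ]
  f1 <- fit_ps_model(d)
  set.seed(1)
  f2 <- fit_ps_model(d[sample(nrow(d)), ])
  expect_identical(f1$selected_covariates, f2$selected_covariates)
  expect_equal(sort(f1$ps), sort(f2$ps), tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("under MCAR, backward-AIC keeps little and the model has no signal", {
  zero <- setNames(rep(0, 6), c("age","education","padl","iadl","mmse","moca"))
  cfg <- sim_config(nonresp_coefs = zero, nonresp_status_boost = 0,
                    nonresp_intercept = qlogis(0.25))
  kept <- vapply(1:20, function(s) {
    sv <- generate_survey(cfg, n_total = 5000, seed = 400 + s)
    length(fit_ps_model(sv)$selected_covariates)
  }, numeric(1))
  # a null covariate survives backward-AIC only when its deviance
  # improvement exceeds 2, i.e. with probability P(chisq_1 > 2) ~ 0.16;
  # the average retained count must sit near 6 * 0.16, far below the
  # candidate-set size
  expect_lt(mean(kept), 2)
})

test_that("coefficient recovery under the published generating model", {
  for (s in 1:3) {
    x <- draw_covariates(4445, seed = 500 + s)
    lp <- REF_PS$intercept +
      as.matrix(x[, names(REF_PS$coefficients)]) %*% REF_PS$coefficients
    d <- cbind(id = as.character(seq_len(nrow(x))), x)
    d$phase <- "phase2"
    d$responded <- runif(nrow(x)) > plogis(lp)
    d$diagnosis <- ifelse(d$responded, "normal", "missing")
    fit <- fit_ps_model(d, names(REF_PS$coefficients), stepwise = FALSE)
    se <- sqrt(diag(fit$vcov))[names(REF_PS$coefficients)]
    expect_true(all(abs(fit$coefficients - REF_PS$coefficients) < 3 * se))
  }
})

test_that("degenerate response patterns are diagnosed", {
  d <- make_records(diagnoses = rep("normal", 50))
  expect_error(fit_ps_model(d), "at least 2")
  # quasi-separation on one covariate is named
  set.seed(23)
  n <- 200
  sep <- data.frame(id = as.character(1:n), age = rnorm(n), education = rnorm(n),
                    padl = rnorm(n), iadl = rnorm(n), mmse = rnorm(n),
                    moca = c(rnorm(n / 2, -20), rnorm(n / 2, 20)),
                    phase = "phase2",
                    responded = rep(c(TRUE, FALSE), each = n / 2))
  sep$diagnosis <- ifelse(sep$responded, "normal", "missing")
  expect_error(fit_ps_model(sep, "moca"), "separation.*moca")
})

test_that("balance table: SMD formula, degenerate SD, and the published MMSE row", {
  # identical groups: every SMD is zero
  resp <- make_records(diagnoses = rep(c("normal", "mci"), 20))
  dup <- resp
  dup$responded <- FALSE
  dup$diagnosis <- "missing"
  dup$id <- paste0(dup$id, "b")
  bt <- balance_table(rbind(resp, dup))
  expect_true(all(bt$smd == 0))

  # hand formula: means 0 and 1, both sample SDs 1 -> SMD 1
  x1 <- as.numeric(scale(rnorm(100)))
  x0 <- as.numeric(scale(rnorm(100))) + 1
  d <- make_records(diagnoses = rep("normal", 100), n_nonresp = 100,
                    covs = list(moca = c(x1, x0)))
  bt2 <- balance_table(d, covariates = "moca")
  expect_equal(bt2$smd, 1, tolerance = 1e-10)

  # published MMSE imbalance: 24.91 vs 24.15 at common SD ~5.1 -> SMD ~0.149
  set.seed(24)
  d3 <- make_records(diagnoses = rep("normal", 4e4), n_nonresp = 4e4,
                     covs = list(mmse = c(rnorm(4e4, 24.91, 5.1),
                                          rnorm(4e4, 24.15, 5.1))))
  bt3 <- balance_table(d3, covariates = "mmse")
  expect_lt(abs(bt3$smd - 0.149), 0.02)
  expect_lt(bt3$p_value, 0.001)

  # zero pooled SD: flagged, SMD reported as 0
  d4 <- make_records(diagnoses = rep("normal", 10), n_nonresp = 10,
                     covs = list(iadl = rep(5, 20)))
  expect_warning(bt4 <- balance_table(d4, covariates = "iadl"), "pooled SD")
  expect_equal(bt4$smd, 0)
  expect_true(bt4$degenerate)
})

test_that("PS distribution comparison: null calibration, power, MNAR direction", {
  # permuted labels: p-values are uniform
  set.seed(25)
  ps <- runif(400)
  pvals <- vapply(1:100, function(i) {
    resp <- sample(rep(c(TRUE, FALSE), 200))
    m <- structure(list(ps = ps, responded = resp), class = "ps_model_fit")
    compare_ps_distributions(m)$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.10), 0.16)

  # one-SD location shift at n = 200 per group is always detected
  set.seed(26)
  m2 <- structure(list(ps = plogis(c(rnorm(200), rnorm(200, 1))),
                       responded = rep(c(TRUE, FALSE), each = 200)),
                  class = "ps_model_fit")
  expect_lt(compare_ps_distributions(m2)$p_value, 0.001)

  # the calibrated MNAR survey shows higher scores among non-responders
  sv <- default_survey(seed = 27, n = 8246)
  cmp <- compare_ps_distributions(fit_ps_model(sv))
  expect_identical(cmp$higher_group, "nonresponders")
  expect_lt(cmp$p_value, 0.001)
})
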