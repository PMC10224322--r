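test_that("simple estimation matches the binomial closed form and a counting oracle", {
  d <- make_records(diagnoses = c(rep("dementia", 20), rep("normal", 80)))
  se <- estimate_se(d)
  dem <- se[se$category == "dementia", ]
  expect_equal(dem$point, 20)
  expect_equal(dem$sd, 100 * sqrt(0.2 * 0.8 / 100), tolerance = 1e-12)

  all_norm <- estimate_se(make_records(diagnoses = rep("normal", 30)))
  expect_equal(all_norm$point[all_norm$category == "dementia"], 0)
  expect_equal(all_norm$sd[all_norm$category == "dementia"], 0)

  # counting oracle over random tiny strata
  set.seed(40)
  for (i in 1:100) {
    dx <- sample(c("normal", "mci", "dementia"), sample(3:40, 1),
                 replace = TRUE)
    nr <- sample(0:10, 1)
    d <- make_records(diagnoses = dx, n_nonresp = nr)
    se <- estimate_se(d)
    for (cat in c("normal", "mci", "dementia"))
      expect_equal(se$point[se$category == cat],
                   100 * sum(dx == cat) / length(dx), tolerance = 1e-12)
  }
  expect_error(estimate_se(make_records(n_nonresp = 5)), "no responders")
})

test_that("ordinal model: intercept-only MLE, normalization, recovery", {
  # covariate-free data with exact frequencies (0.5, 0.3, 0.2):
  # cutpoints at logit(0.5) = 0 and logit(0.8)
  d <- make_records(diagnoses = rep(c("normal", "mci", "dementia"),
                                    c(500, 300, 200)))
  fit <- fit_ordinal_model(d, candidate_covariates = character(0))
  expect_equal(unname(fit$zeta), c(0, qlogis(0.8)), tolerance = 1e-3)

  # predicted probabilities sum to one on a covariate grid
  sv <- default_survey(seed = 41, n = 2000)
  resp <- sv$records[sv$records$responded %in% TRUE, ]
  fit2 <- fit_ordinal_model(resp)
  grid <- resp[sample.int(nrow(resp), 100), ]
  pr <- predict_ordinal_probs(fit2, grid)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_true(all(pr >= 0))

  # parameter recovery from a known proportional-odds truth at n = 2000
  truth <- c(moca = -0.2, mmse = -0.05)
  for (s in 1:3) {
    x <- draw_covariates(2000, seed = 600 + s)
    eta <- as.matrix(x[, names(truth)]) %*% truth
    u <- runif(2000)
    p1 <- plogis(-7.5 - eta)          # cutpoints -7.5, -5
    p2 <- plogis(-5.0 - eta)
    x$diagnosis <- c("normal", "mci", "dementia")[1 + (u > p1) + (u > p2)]
    fitr <- fit_ordinal_model(x, names(truth), stepwise = FALSE)
    se <- sqrt(diag(fitr$vcov))[names(truth)]
    expect_true(all(abs(fitr$coefficients - truth) < 3 * se))
  }

  # single observed category is a degenerate fit
  expect_error(fit_ordinal_model(make_records(diagnoses = rep("mci", 40))),
               class = "pssprev_degenerate")
})

test_that("two-category strata use the binomial reduction consistently", {
  d <- make_records(diagnoses = rep(c("normal", "mci"), c(60, 40)))
  fit <- fit_ordinal_model(d, candidate_covariates = character(0))
  expect_equal(fit$levels, c("normal", "mci"))
  pr <- predict_ordinal_probs(fit, d[1:5, ])
  expect_equal(unname(pr[, "dementia"]), rep(0, 5))
  expect_equal(unname(pr[1, "normal"]), 0.6, tolerance = 1e-6)
})

test_that("regression estimation: fill-in identities and simulation accuracy", {
  # zero non-responders: RE point equals SE point exactly
  sv <- default_survey(seed = 42, n = 1200)
  d <- sv$records[sv$records$phase == "phase2", ]
  d$responded <- TRUE
  d$diagnosis <- d$true_status
  re <- suppressWarnings(estimate_re(d, B = 0))
  se <- estimate_se(d)
  expect_equal(re$point, se$point, tolerance = 1e-12)

  # plug-in consistency: a non-responder sharing a responder's covariates
  # receives that responder's fitted probabilities
  resp <- sv$records[sv$records$responded %in% TRUE, ]
  fit <- fit_ordinal_model(resp)
  clone <- resp[7, , drop = FALSE]
  expect_equal(predict_ordinal_probs(fit, clone),
               predict_ordinal_probs(fit, resp[7, , drop = FALSE]))

  # MCAR fill-in at stratum scale recovers the complete-data prevalence
  ok <- vapply(1:6, function(s) {
    sv2 <- default_survey(seed = 800 + s, n = 1700)
    d2 <- utils::head(sv2$records[sv2$records$phase == "phase2", ], 889)
    d2$responded <- TRUE
    d2$diagnosis <- d2$true_status
    true_prev <- 100 * mean(d2$diagnosis == "dementia")
    set.seed(s)
    drop <- sample(nrow(d2), round(0.3 * nrow(d2)))
    d2$responded[drop] <- FALSE
    d2$diagnosis[drop] <- "missing"
    re2 <- estimate_re(d2, B = 60)
    r <- re2[re2$category == "dementia", ]
    abs(r$point - true_prev) < 3 * max(r$sd, 0.5)
  }, logical(1))
  expect_gte(sum(ok), 5)
})

test_that("single imputation: point-mass, multinomial frequencies, determinism", {
  # degenerate probabilities always impute the certain category
  fit <- fixed_prob_fit(c(1e-12, 1e-12, 1 - 2e-12))
  nr <- make_records(n_nonresp = 6)
  nr <- nr[nr$phase == "phase2", ]
  set.seed(50)
  expect_true(all(impute_once(fit, nr) == "dementia"))

  # multinomial sampling oracle at fixed parameters
  fit2 <- fixed_prob_fit(c(0.5, 0.3, 0.2))
  big <- make_records(n_nonresp = 1e4)
  big <- big[big$phase == "phase2", ]
  set.seed(51)
  imp <- impute_once(fit2, big)
  freq <- prop.table(table(factor(imp, c("normal", "mci", "dementia"))))
  expect_true(all(abs(as.numeric(freq) - c(0.5, 0.3, 0.2)) < 0.015))

  # same seed, same imputation
  set.seed(52); a <- impute_once(fit2, big)
  set.seed(52); b <- impute_once(fit2, big)
  expect_identical(a, b)
})

test_that("Rubin's rules match the hand computation", {
  pooled <- rubin_pool(points = c(10, 20), within_vars = c(1, 1))
  expect_equal(pooled$point, 15)
  # between-variance ((10-15)^2 + (20-15)^2)/1 = 50; total 1 + 1.5*50 = 76
  expect_equal(pooled$variance, 76)
  expect_equal(pooled$sd, sqrt(76))
})

test_that("REMI: no-missing identity and agreement with RE", {
  sv <- default_survey(seed = 43, n = 1200)
  d <- sv$records[sv$records$phase == "phase2", ]
  d$responded <- TRUE
  d$diagnosis <- d$true_status
  remi <- suppressWarnings(estimate_remi(d, m = 5))
  se <- estimate_se(d)
  expect_equal(remi$point, se$point, tolerance = 1e-12)

  # REMI and RE estimate the same estimand on a default stratum
  d2 <- sv$records[sv$records$phase == "phase2", ]
  set.seed(53)
  remi2 <- estimate_remi(d2, m = 30)
  re2 <- estimate_re(d2, B = 0)
  r_remi <- remi2[remi2$category == "dementia", ]
  r_re <- re2[re2$category == "dementia", ]
  expect_lt(abs(r_remi$point - r_re$point), 2 * r_remi$sd)
})

test_that("estimates of the three categories always sum to 100", {
  sv <- default_survey(seed = 44, n = 1500)
  d <- sv$records[sv$records$phase == "phase2", ]
  set.seed(54)
  for (est in list(estimate_se(d), estimate_re(d, B = 0),
                   estimate_remi(d, m = 4)))
    expect_equal(sum(est$point), 100, tolerance = 1e-8)
})

test_that("complete-case prevalence over the diagnosed cohort", {
  # printed two-phase flow: 3801 screen-negatives; 589/1979/707 responders
  d <- make_records(n1 = 3801,
                    diagnoses = rep(c("normal", "mci", "dementia"),
                                    c(589, 1979, 707)),
                    n_nonresp = 1170)
  cc <- complete_case_prevalence(d)
  expect_equal(cc$point[cc$category == "dementia"], 100 * 707 / 7076,
               tolerance = 1e-12)
  expect_equal(cc$n_basis[1], 7076)

  all_dem <- complete_case_prevalence(
    make_records(diagnoses = rep("dementia", 12)))
  expect_equal(all_dem$point[all_dem$category == "dementia"], 100)

  # with no missing data it equals SE on the whole phase-II cohort
  sv <- default_survey(seed = 45, n = 800)
  d2 <- sv$records
  d2$responded[d2$phase == "phase2"] <- TRUE
  d2$diagnosis <- ifelse(d2$phase == "phase2", d2$true_status, "normal")
  cc2 <- complete_case_prevalence(d2)
  expect_equal(sum(cc2$point), 100, tolerance = 1e-10)
})
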