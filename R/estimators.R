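# Stratum-level prevalence estimators.
#
# SE:   share of each category among the stratum's responders, binomial SD.
# RE:   responders observed + non-responders filled in with their predicted
#       category probabilities from the ordinal model; SD by stratified
#       bootstrap of the responders.
# REMI: m proper imputations from the ordinal model's approximate posterior,
#       SE-style estimate on each completed stratum, pooled by Rubin's
#       rules.
# All points are percentages; variances are in squared percentage points.

category_shares <- function(diagnoses) {
  vapply(STATUS_LEVELS, function(s) mean(diagnoses == s), 0)
}

#' Simple (binomial) stratum estimator
#'
#' @param stratum_records data.frame of one stratum's phase-II subjects.
#' @param scope label recorded on the estimates (default "stratum").
#' @return data.frame of three \code{prevalence_estimate} rows (normal,
#'   mci, dementia); \code{sd = sqrt(p(1-p)/m) * 100} with m responders.
#' @export
estimate_se <- function(stratum_records, scope = "stratum") {
  resp <- stratum_records[stratum_records$responded %in% TRUE, , drop = FALSE]
  m <- nrow(resp)
  if (m == 0)
    stop(structure(class = c("pssprev_no_responders", "error", "condition"),
                   list(message = "stratum has no responders; merge strata",
                        call = sys.call(-1))))
  p <- category_shares(resp$diagnosis)
  do.call(rbind, lapply(STATUS_LEVELS, function(s)
    prevalence_estimate(s, scope, "SE", 100 * p[[s]],
                        100 * sqrt(p[[s]] * (1 - p[[s]]) / m), m)))
}

re_point <- function(records, fit) {
  resp <- records[records$responded %in% TRUE, , drop = FALSE]
  nonresp <- records[records$responded %in% FALSE, , drop = FALSE]
  obs <- vapply(STATUS_LEVELS, function(s) sum(resp$diagnosis == s), 0)
  fill <- if (nrow(nonresp) > 0)
    colSums(predict_ordinal_probs(fit, nonresp)) else
    stats::setNames(rep(0, 3), STATUS_LEVELS)
  100 * (obs + fill) / nrow(records)
}

#' Regression (ordinal fill-in) stratum estimator
#'
#' Observed responder counts plus model-predicted category probabilities
#' for each non-responder, divided by the stratum size. The SD comes from a
#' stratified bootstrap: resample responders with replacement, refit the
#' selected ordinal model, re-predict the (fixed) non-responders.
#'
#' @param stratum_records data.frame of one stratum's phase-II subjects.
#' @param candidate_covariates covariates offered to the ordinal model.
#' @param B bootstrap replicates for the SD (default 200; 0 skips the
#'   bootstrap and reports \code{sd = NA}).
#' @param scope label recorded on the estimates.
#' @param stepwise forwarded to [fit_ordinal_model()].
#' @return data.frame of three estimate rows; falls back to [estimate_se()]
#'   (with \code{fallback = TRUE} and a warning) when the ordinal fit is
#'   degenerate.
#' @export
estimate_re <- function(stratum_records, candidate_covariates = COVARIATES,
                        B = 200, scope = "stratum", stepwise = TRUE) {
  n <- nrow(stratum_records)
  resp <- stratum_records[stratum_records$responded %in% TRUE, , drop = FALSE]
  fit <- tryCatch(
    fit_ordinal_model(resp, candidate_covariates, stepwise = stepwise),
    pssprev_degenerate = function(e) e)
  if (inherits(fit, "condition")) {
    warning("RE fell back to SE: ", conditionMessage(fit))
    out <- estimate_se(stratum_records, scope)
    out$method <- "RE"; out$fallback <- TRUE
    return(out)
  }
  pt <- re_point(stratum_records, fit)
  sds <- stats::setNames(rep(NA_real_, 3), STATUS_LEVELS)
  if (B > 0) {
    draws <- matrix(NA_real_, B, 3, dimnames = list(NULL, STATUS_LEVELS))
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(resp), replace = TRUE)
      refit <- tryCatch(
        fit_ordinal_model(resp[idx, , drop = FALSE],
                          fit$selected_covariates, stepwise = FALSE),
        error = function(e) NULL)
      if (is.null(refit)) next
      boot_rec <- rbind(resp[idx, , drop = FALSE],
                        stratum_records[stratum_records$responded %in% FALSE, ,
                                        drop = FALSE])
      draws[b, ] <- re_point(boot_rec, refit)
    }
    ok <- stats::complete.cases(draws)
    if (sum(ok) >= max(10, B / 4)) {
      sds <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
    } else {
      warning("bootstrap for the RE standard deviation failed in ",
              B - sum(ok), "/", B, " replicates; sd reported as NA")
    }
  }
  do.call(rbind, lapply(STATUS_LEVELS, function(s)
    prevalence_estimate(s, scope, "RE", pt[[s]], sds[[s]], n)))
}

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' Point = mean of the per-imputation points; total variance = mean
#' within-imputation variance + (1 + 1/m) x between-imputation variance,
#' with the between-variance the sample variance of the points.
#'
#' @param points per-imputation point estimates (percent).
#' @param within_vars per-imputation variances (squared percent).
#' @return list with \code{point}, \code{variance} and \code{sd}.
#' @export
rubin_pool <- function(points, within_vars) {
  m <- length(points)
  stopifnot(m >= 2, length(within_vars) == m)
  between <- stats::var(points)
  total <- mean(within_vars) + (1 + 1 / m) * between
  list(point = mean(points), variance = total, sd = sqrt(total))
}

#' Regression estimation with multiple imputation (REMI)
#'
#' Completes the stratum \code{m} times with [impute_once()] draws, computes
#' the simple prevalence and its binomial variance on each completed
#' stratum, and pools by Rubin's rules: point = mean of the m points, total
#' variance = mean within-imputation variance + (1 + 1/m) x between-
#' imputation variance.
#'
#' @param stratum_records data.frame of one stratum's phase-II subjects.
#' @param m number of imputations (>= 2; default 20).
#' @param candidate_covariates covariates offered to the ordinal model.
#' @param scope label recorded on the estimates.
#' @param stepwise forwarded to [fit_ordinal_model()].
#' @return data.frame of three estimate rows; falls back to SE (flagged)
#'   when the ordinal fit is degenerate.
#' @export
estimate_remi <- function(stratum_records, m = 20,
                          candidate_covariates = COVARIATES,
                          scope = "stratum", stepwise = TRUE) {
  stopifnot(m >= 2)
  n <- nrow(stratum_records)
  resp <- stratum_records[stratum_records$responded %in% TRUE, , drop = FALSE]
  nonresp <- stratum_records[stratum_records$responded %in% FALSE, , drop = FALSE]
  fit <- tryCatch(
    fit_ordinal_model(resp, candidate_covariates, stepwise = stepwise),
    pssprev_degenerate = function(e) e)
  if (inherits(fit, "condition")) {
    warning("REMI fell back to SE: ", conditionMessage(fit))
    out <- estimate_se(stratum_records, scope)
    out$method <- "REMI"; out$fallback <- TRUE
    return(out)
  }
  pts <- matrix(NA_real_, m, 3, dimnames = list(NULL, STATUS_LEVELS))
  wvar <- matrix(NA_real_, m, 3, dimnames = list(NULL, STATUS_LEVELS))
  for (j in seq_len(m)) {
    completed <- c(resp$diagnosis, impute_once(fit, nonresp))
    p <- category_shares(completed)
    pts[j, ] <- 100 * p
    wvar[j, ] <- 100^2 * p * (1 - p) / n
  }
  do.call(rbind, lapply(STATUS_LEVELS, function(s) {
    pooled <- rubin_pool(pts[, s], wvar[, s])
    prevalence_estimate(s, scope, "REMI", pooled$point, pooled$sd, n)
  }))
}

#' Complete-case prevalence over the diagnosed cohort
#'
#' The naive estimate that motivates the whole framework: category share
#' among all subjects with an observed diagnosis (phase-I screen-negatives,
#' counted as normal, plus phase-II responders), with a binomial SD. Under
#' informative non-response this underestimates disease prevalence.
#'
#' @param dataset a \code{pss_survey} or participant data.frame.
#' @return data.frame of three estimate rows, scope "overall", method
#'   "complete_case".
#' @export
complete_case_prevalence <- function(dataset) {
  d <- if (inherits(dataset, "pss_survey")) dataset$records else dataset
  diagnosed <- d[d$diagnosis != "missing", , drop = FALSE]
  n <- nrow(diagnosed)
  if (n == 0) stop("no diagnosed subjects")
  p <- category_shares(diagnosed$diagnosis)
  do.call(rbind, lapply(STATUS_LEVELS, function(s)
    prevalence_estimate(s, "overall", "complete_case", 100 * p[[s]],
                        100 * sqrt(p[[s]] * (1 - p[[s]]) / n), n)))
}
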