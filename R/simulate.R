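# Synthetic two-phase survey generator.
#
# The generator mirrors the design of large dementia prevalence surveys: a
# cheap phase-I screen labels part of the cohort "normal", the rest undergo
# definitive phase-II diagnosis, and a share of phase-II subjects fail to
# complete the battery. Non-response is drawn from a logistic model on the
# observed covariates plus the latent status itself, so the missingness can
# be made MCAR, MAR-given-covariates, or MNAR by configuration.

#' Draw correlated cognitive and functional covariates
#'
#' Samples age, education, PADL, IADL, MMSE and MoCA from a multivariate
#' normal with the configured means, SDs and correlation matrix. MMSE and
#' MoCA are clipped to their instrument range [0, 30] unless
#' \code{config$clip_scores} is FALSE; clipping truncates the upper tail and
#' so biases those two sample means slightly below the configured values.
#'
#' @param config a [sim_config()].
#' @param n number of subjects.
#' @return data.frame with the six covariate columns.
#' @export
generate_covariates <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 6))
    names(out) <- COVARIATES
    return(out)
  }
  D <- diag(config$cov_sds, 6)
  Sigma <- D %*% config$cov_corr %*% D
  X <- MASS::mvrnorm(n, mu = config$cov_means, Sigma = Sigma)
  X <- matrix(X, nrow = n, dimnames = list(NULL, COVARIATES))
  out <- as.data.frame(X)
  if (isTRUE(config$clip_scores)) {
    out$mmse <- pmin(pmax(out$mmse, 0), 30)
    out$moca <- pmin(pmax(out$moca, 0), 30)
  }
  if (isTRUE(config$round_scores))
    out[] <- lapply(out, function(v) round(v))
  out
}

status_linear_predictor <- function(covariates, config) {
  b <- config$status_coefs
  as.vector(as.matrix(covariates[, names(b), drop = FALSE]) %*% b)
}

#' Draw latent three-level cognitive status
#'
#' Latent status follows a proportional-odds model on the covariates:
#' P(status <= k) = plogis(cutpoint_k - x'beta), k = 1 (normal), 2 (MCI),
#' with dementia as the upper residual category.
#'
#' @param covariates data.frame from [generate_covariates()].
#' @param config a [sim_config()].
#' @return character vector in \code{c("normal", "mci", "dementia")}.
#' @export
assign_true_status <- function(covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(covariates)
  if (n == 0) return(character(0))
  lp <- status_linear_predictor(covariates, config)
  p1 <- stats::plogis(config$status_cutpoints[1] - lp)
  p2 <- stats::plogis(config$status_cutpoints[2] - lp)
  u <- stats::runif(n)
  STATUS_LEVELS[1L + (u > p1) + (u > p2)]
}

#' Apply the phase-I screen
#'
#' Truly normal subjects are labelled \code{phase1_normal} with probability
#' \code{screen_specificity}; impaired subjects proceed to phase II with
#' probability \code{screen_sensitivity}. Impaired subjects missed by the
#' screen are false negatives: they carry the label \code{phase1_normal} and
#' a (wrong) diagnosis of "normal", mirroring the working assumption of
#' two-phase surveys that screen-negatives are disease-free.
#'
#' @param true_status character vector of latent statuses.
#' @param config a [sim_config()].
#' @return character vector in \code{c("phase1_normal", "phase2")}.
#' @export
apply_phase1_screen <- function(true_status, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(true_status)
  if (n == 0) return(character(0))
  u <- stats::runif(n)
  normal <- true_status == "normal"
  phase2 <- ifelse(normal, u > config$screen_specificity,
                   u <= config$screen_sensitivity)
  ifelse(phase2, "phase2", "phase1_normal")
}

#' Draw phase-II non-response
#'
#' For each phase-II subject the non-response probability is
#' plogis(intercept + x'gamma + boost * level), with level = 0, 1, 2 for
#' normal, MCI, dementia. A positive \code{nonresp_status_boost} makes the
#' missingness depend on the (unobserved) diagnosis itself — MNAR.
#'
#' @param records data.frame with covariates, \code{phase} and
#'   \code{true_status} columns.
#' @param config a [sim_config()].
#' @return logical vector \code{responded} (NA for phase-I subjects).
#' @export
apply_nonresponse <- function(records, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(records)
  responded <- rep(NA, n)
  ph2 <- which(records$phase == "phase2")
  if (length(ph2) == 0) return(responded)
  g <- config$nonresp_coefs
  lp <- config$nonresp_intercept +
    as.vector(as.matrix(records[ph2, names(g), drop = FALSE]) %*% g) +
    config$nonresp_status_boost *
      (match(records$true_status[ph2], STATUS_LEVELS) - 1)
  responded[ph2] <- stats::runif(length(ph2)) > stats::plogis(lp)
  responded
}

#' Generate a complete synthetic two-phase survey
#'
#' Runs the full generator pipeline (covariates, latent status, phase-I
#' screen, phase-II non-response) under the configured seed. The returned
#' records keep \code{true_status} purely for validation; no estimator in
#' the package reads it.
#'
#' @param config a [sim_config()].
#' @param n_total optional override of \code{config$n_total}.
#' @param seed optional override of \code{config$seed}.
#' @return object of class \code{pss_survey}: list with \code{records}
#'   (participant data.frame), \code{counts} (phase and response totals) and
#'   \code{truth} (true prevalences overall and in phase II, and the seed).
#' @examples
#' sv <- generate_survey(sim_config(n_total = 300, seed = 7))
#' sv$counts
#' @export
generate_survey <- function(config, n_total = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- if (is.null(n_total)) config$n_total else n_total
  sd0 <- if (is.null(seed)) config$seed else seed
  records <- with_seed(stage_seed(sd0, "simulate"), {
    covs <- generate_covariates(config, n)
    true_status <- assign_true_status(covs, config)
    phase <- apply_phase1_screen(true_status, config)
    rec <- cbind(data.frame(id = sprintf("S%06d", seq_len(n))), covs)
    rec$phase <- phase
    rec$true_status <- true_status
    rec$responded <- apply_nonresponse(rec, config)
    rec$diagnosis <- ifelse(rec$phase == "phase1_normal", "normal",
                            ifelse(rec$responded, rec$true_status, "missing"))
    rec
  })
  if (n == 0) {
    records <- data.frame(id = character(0))
    for (v in COVARIATES) records[[v]] <- numeric(0)
    records$phase <- character(0); records$true_status <- character(0)
    records$responded <- logical(0); records$diagnosis <- character(0)
  }
  ph2 <- records$phase == "phase2"
  counts <- list(
    n_total = n,
    n_phase1 = sum(!ph2),
    n_phase2 = sum(ph2),
    n_responders = sum(ph2 & records$responded %in% TRUE),
    n_nonresponders = sum(ph2 & records$responded %in% FALSE))
  prev <- function(idx) {
    if (!any(idx)) return(stats::setNames(rep(NA_real_, 3), STATUS_LEVELS))
    100 * vapply(STATUS_LEVELS,
                 function(s) mean(records$true_status[idx] == s), 0)
  }
  truth <- list(
    seed = sd0,
    true_prev_overall = prev(rep(TRUE, n)),
    true_prev_phase2 = prev(ph2),
    # "apparent" truth under the two-phase convention that phase-I
    # screen-negatives are disease-free (false negatives count as normal)
    apparent_prev_overall = if (n > 0)
      prev(ph2) * counts$n_phase2 / n else prev(ph2))
  if (n > 0) {
    ap <- truth$apparent_prev_overall
    ap["normal"] <- 100 - ap["mci"] - ap["dementia"]
    truth$apparent_prev_overall <- ap
  }
  structure(list(records = records, counts = counts, truth = truth,
                 config = config),
            class = "pss_survey")
}

#' @export
print.pss_survey <- function(x, ...) {
  cat("Synthetic two-phase survey:", x$counts$n_total, "subjects\n")
  cat("  phase I normal:", x$counts$n_phase1,
      " phase II:", x$counts$n_phase2, "\n")
  cat("  responders:", x$counts$n_responders,
      " non-responders:", x$counts$n_nonresponders, "\n")
  invisible(x)
}

#' Write a survey to disk
#'
#' Writes the participant table as CSV and a sidecar truth file (true
#' prevalences, seed, configuration echo) as JSON.
#'
#' @param survey a \code{pss_survey}.
#' @param prefix output path prefix; writes \code{<prefix>_participants.csv}
#'   and \code{<prefix>_truth.json}.
#' @return named character vector of the two paths, invisibly.
#' @export
write_survey <- function(survey, prefix) {
  stopifnot(inherits(survey, "pss_survey"))
  csv <- paste0(prefix, "_participants.csv")
  js <- paste0(prefix, "_truth.json")
  utils::write.csv(survey$records, csv, row.names = FALSE, na = "")
  cfg <- unclass(survey$config)
  cfg$cov_corr <- NULL
  jsonlite::write_json(
    list(counts = survey$counts, truth = survey$truth, config = cfg),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(participants = csv, truth = js))
}
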