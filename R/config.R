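#' Simulation configuration for the synthetic two-phase survey
#'
#' Bundles every parameter of the synthetic-survey generator: covariate
#' moments and correlations, the latent proportional-odds disease model, the
#' phase-I screen operating characteristics, and the logistic non-response
#' mechanism whose dependence on latent status (`nonresp_status_boost`) is
#' the MNAR knob. Defaults (loaded from the packaged calibration file) are
#' calibrated so that, at the default cohort size, the phase-II fraction,
#' non-response fraction, responder diagnosis mix and responder versus
#' non-responder covariate imbalance resemble a large veteran dementia
#' survey.
#'
#' @param ... named overrides of any default field. Recognised fields:
#'   \describe{
#'     \item{n_total}{cohort size before the phase-I screen.}
#'     \item{cov_means, cov_sds}{named numeric vectors over
#'       \code{age, education, padl, iadl, mmse, moca}.}
#'     \item{cov_corr}{6x6 correlation matrix in the same order.}
#'     \item{status_coefs}{named coefficients of the latent
#'       proportional-odds status model (positive = more impaired).}
#'     \item{status_cutpoints}{two increasing cutpoints separating
#'       normal | MCI | dementia on the latent logistic scale.}
#'     \item{screen_sensitivity}{probability an impaired subject is sent to
#'       phase II.}
#'     \item{screen_specificity}{probability a truly normal subject is
#'       labelled normal in phase I.}
#'     \item{nonresp_intercept, nonresp_coefs}{logistic non-response model on
#'       covariates, fitted on the log-odds scale.}
#'     \item{nonresp_status_boost}{additive log-odds of non-response per
#'       latent status level (0 = normal, 1 = MCI, 2 = dementia); zero makes
#'       the mechanism ignorable given covariates.}
#'     \item{clip_scores}{clip MMSE and MoCA to [0, 30] (default TRUE).}
#'     \item{round_scores}{round all scores to integers (default FALSE).}
#'     \item{seed}{RNG seed fixing the generated dataset bit-for-bit.}
#'   }
#' @return an object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(n_total = 500, seed = 1)
#' cfg$screen_sensitivity
#' @export
sim_config <- function(...) {
  cfg <- default_sim_config()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_sim_config(cfg)
}

#' Default generator configuration
#'
#' Reads the packaged calibration file \code{extdata/default_config.yaml};
#' all calibration constants live there rather than in code.
#'
#' @return a \code{sim_config} object.
#' @export
default_sim_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "pssprev")
  if (path == "") stop("packaged default_config.yaml not found")
  read_sim_config(path)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file with \code{sim_config} fields; the correlation
#'   matrix is stored as a list of rows.
#' @return a validated \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("cov_means", "cov_sds", "status_coefs", "nonresp_coefs"))
    raw[[nm]] <- unlist(raw[[nm]])
  raw$cov_corr <- do.call(rbind, raw$cov_corr)
  dimnames(raw$cov_corr) <- list(COVARIATES, COVARIATES)
  raw$status_cutpoints <- as.numeric(unlist(raw$status_cutpoints))
  validate_sim_config(raw)
}

#' Write a generator configuration to YAML
#'
#' @param config a \code{sim_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$cov_corr <- lapply(seq_len(nrow(config$cov_corr)),
                         function(i) as.numeric(config$cov_corr[i, ]))
  out$cov_means <- as.list(config$cov_means)
  out$cov_sds <- as.list(config$cov_sds)
  out$status_coefs <- as.list(config$status_coefs)
  out$nonresp_coefs <- as.list(config$nonresp_coefs)
  yaml::write_yaml(out, path)
  invisible(path)
}

validate_sim_config <- function(cfg) {
  req <- c("n_total", "cov_means", "cov_sds", "cov_corr", "status_coefs",
           "status_cutpoints", "screen_sensitivity", "screen_specificity",
           "nonresp_intercept", "nonresp_coefs", "nonresp_status_boost",
           "clip_scores", "round_scores", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("sim_config missing fields: ",
                         paste(miss, collapse = ", "))
  stopifnot(cfg$n_total >= 0)
  for (nm in c("cov_means", "cov_sds")) {
    if (!all(COVARIATES %in% names(cfg[[nm]])))
      stop(nm, " must name all of: ", paste(COVARIATES, collapse = ", "))
    cfg[[nm]] <- cfg[[nm]][COVARIATES]
  }
  if (any(cfg$cov_sds < 0)) stop("cov_sds must be non-negative")
  R <- cfg$cov_corr
  if (!is.matrix(R) || !identical(dim(R), c(6L, 6L)))
    stop("cov_corr must be a 6x6 matrix")
  if (max(abs(R - t(R))) > 1e-8) stop("cov_corr must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("cov_corr is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  if (length(cfg$status_cutpoints) != 2 || diff(cfg$status_cutpoints) <= 0)
    stop("status_cutpoints must be two strictly increasing values")
  for (p in c("screen_sensitivity", "screen_specificity"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (!all(names(cfg$status_coefs) %in% COVARIATES) ||
      !all(names(cfg$nonresp_coefs) %in% COVARIATES))
    stop("status_coefs / nonresp_coefs must be named by covariates")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic two-phase survey configuration\n")
  cat("  n_total:", x$n_total, " seed:", x$seed, "\n")
  cat("  screen sens/spec:", x$screen_sensitivity, "/",
      x$screen_specificity, "\n")
  cat("  non-response status boost (MNAR):", x$nonresp_status_boost, "\n")
  invisible(x)
}
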