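# End-to-end pipeline: read/validate participants, fit, stratify, estimate,
# pool, and write a report directory. Every number in the written CSVs is
# reproducible by calling the module functions directly with the same seed.

#' Read a participant table from CSV
#'
#' @param path CSV with columns id, age, education, padl, iadl, mmse, moca,
#'   phase, responded, diagnosis (and optionally true_status).
#' @return participant data.frame.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if ("responded" %in% names(d) && !is.logical(d$responded))
    d$responded <- as.logical(d$responded)
  d
}

#' Validate a participant table
#'
#' Schema and consistency checks: required columns, numeric covariates,
#' known phase/diagnosis labels, the phase/response/diagnosis invariants of
#' a two-phase survey, and duplicate ids. Problems are split into errors
#' (the pipeline refuses to run) and warnings.
#'
#' @param x participant data.frame, \code{pss_survey}, or a CSV path.
#' @return object of class \code{validation_report}: list of \code{errors}
#'   and \code{warnings} (character vectors) and \code{n} rows checked.
#' @export
validate_input <- function(x) {
  if (is.character(x)) x <- read_survey(x)
  if (inherits(x, "pss_survey")) x <- x$records
  errors <- character(0); warns <- character(0)
  need <- c("id", COVARIATES, "phase", "responded", "diagnosis")
  miss <- setdiff(need, names(x))
  if (length(miss))
    errors <- c(errors, paste0("missing required column(s): ",
                               paste(miss, collapse = ", ")))
  if (!length(miss)) {
    for (v in COVARIATES) {
      bad <- which(!is.na(x[[v]]) & is.na(suppressWarnings(as.numeric(x[[v]]))))
      if (length(bad))
        errors <- c(errors, paste0("non-numeric ", v, " at row(s): ",
                                   paste(utils::head(bad, 5), collapse = ", ")))
      nas <- which(is.na(x[[v]]))
      if (length(nas))
        errors <- c(errors, paste0("missing ", v, " at row(s): ",
                                   paste(utils::head(nas, 5), collapse = ", ")))
    }
    if (anyDuplicated(x$id))
      warns <- c(warns, paste0("duplicate id(s): ",
                               paste(utils::head(unique(x$id[duplicated(x$id)]), 5),
                                     collapse = ", ")))
    badphase <- which(!x$phase %in% c("phase1_normal", "phase2"))
    if (length(badphase))
      errors <- c(errors, paste0("unknown phase label at row(s): ",
                                 paste(utils::head(badphase, 5), collapse = ", ")))
    baddx <- which(!x$diagnosis %in% c(STATUS_LEVELS, "missing"))
    if (length(baddx))
      errors <- c(errors, paste0("unknown diagnosis at row(s): ",
                                 paste(utils::head(baddx, 5), collapse = ", ")))
    p1 <- x$phase == "phase1_normal"
    bad1 <- which(p1 & x$diagnosis != "normal")
    if (length(bad1))
      errors <- c(errors, paste0("phase-I subjects must carry diagnosis ",
                                 "'normal'; row(s): ",
                                 paste(utils::head(bad1, 5), collapse = ", ")))
    ph2 <- x$phase == "phase2"
    badna <- which(ph2 & is.na(x$responded))
    if (length(badna))
      errors <- c(errors, paste0("phase-II subjects need a response ",
                                 "indicator; row(s): ",
                                 paste(utils::head(badna, 5), collapse = ", ")))
    badm <- which(ph2 & x$responded %in% FALSE & x$diagnosis != "missing")
    if (length(badm))
      errors <- c(errors, paste0("non-responders must have diagnosis ",
                                 "'missing'; row(s): ",
                                 paste(utils::head(badm, 5), collapse = ", ")))
    badr <- which(ph2 & x$responded %in% TRUE & !x$diagnosis %in% STATUS_LEVELS)
    if (length(badr))
      errors <- c(errors, paste0("responders must have an observed ",
                                 "diagnosis; row(s): ",
                                 paste(utils::head(badr, 5), collapse = ", ")))
  }
  structure(list(errors = errors, warnings = warns, n = nrow(x)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation of", x$n, "participant rows:",
      length(x$errors), "error(s),", length(x$warnings), "warning(s)\n")
  for (e in x$errors) cat("  ERROR:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

format_estimates <- function(est, digits = 2) {
  est$point <- round_half_up(est$point, digits)
  est$sd <- round_half_up(est$sd, digits)
  est$ci_lo <- round_half_up(est$ci_lo, digits)
  est$ci_hi <- round_half_up(est$ci_hi, digits)
  est
}

#' Run the full analysis pipeline and write a report
#'
#' Orchestrates simulate (optional) -> validate -> propensity fit ->
#' stratify -> estimate -> pool -> report. Writes, under \code{out_prefix}:
#' the augmented participant CSV (\code{ps}, \code{stratum} columns), the
#' PS model JSON, the balance table, the stratum summary, the per-stratum /
#' phase-II / overall estimates CSV, a with-vs-without-stratification
#' comparison CSV, and a run log. Fully reproducible under a fixed seed.
#'
#' @param input participant CSV path, data.frame, or \code{pss_survey};
#'   NULL to simulate from \code{config}.
#' @param config a [sim_config()] used when \code{input} is NULL.
#' @param out_prefix path prefix for outputs; NULL writes nothing.
#' @param k number of PS strata.
#' @param methods estimation methods to run.
#' @param B bootstrap replicates for RE.
#' @param m REMI imputations.
#' @param seed master seed for all stochastic stages.
#' @param compare also run the unstratified arm and write the comparison.
#' @param digits presentation rounding for report CSVs (internal values are
#'   kept at full precision).
#' @return the \code{pss_fit}, augmented with the balance table, the
#'   comparison (if requested), and output paths, invisibly.
#' @export
run_pipeline <- function(input = NULL, config = NULL, out_prefix = NULL,
                         k = 5, methods = c("SE", "RE", "REMI"),
                         B = 200, m = 20, seed = 1, compare = FALSE,
                         digits = 2) {
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  survey <- NULL
  if (is.null(input)) {
    if (is.null(config)) config <- default_sim_config()
    note("simulating survey: n_total = ", config$n_total, ", seed = ", seed)
    survey <- generate_survey(config, seed = seed)
    records <- survey$records
  } else {
    records <- if (is.character(input)) {
      note("reading ", input)
      read_survey(input)
    } else if (inherits(input, "pss_survey")) input$records else input
  }
  rep0 <- validate_input(records)
  if (length(rep0$errors)) {
    print(rep0)
    stop("input validation failed (stage: validate)")
  }
  for (w in rep0$warnings) note("validation warning: ", w)
  fallbacks <- character(0)
  fit <- withCallingHandlers(
    pss_estimate(records, k = k, methods = methods, B = B, m = m,
                 seed = seed),
    warning = function(w) {
      fallbacks <<- c(fallbacks, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (f in fallbacks) note("estimator warning: ", f)
  note("strata sizes: ", paste(fit$assignment$sizes, collapse = ", "))
  balance <- balance_table(records)
  ps_cmp <- if (!is.null(fit$ps_fit)) compare_ps_distributions(fit$ps_fit)
  cmp <- NULL
  if (compare) {
    note("running unstratified comparison arm")
    cmp <- withCallingHandlers(
      pss_estimate(records, k = 1, methods = methods, B = B, m = m,
                   seed = seed),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  paths <- NULL
  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    aug <- records
    ph2 <- aug$phase == "phase2"
    aug$ps <- NA_real_
    aug$stratum <- NA_integer_
    if (!is.null(fit$ps_fit)) aug$ps[ph2] <- fit$ps_fit$ps
    aug$stratum[ph2] <- fit$assignment$stratum_of
    est <- rbind(fit$stratum_estimates, fit$phase2_estimates,
                 fit$overall_estimates)
    if (!is.null(survey)) {
      cc <- complete_case_prevalence(records)
      est <- rbind(est, cc)
    }
    paths <- c(participants = paste0(out_prefix, "_participants.csv"),
               model = paste0(out_prefix, "_ps_model.json"),
               balance = paste0(out_prefix, "_balance.csv"),
               strata = paste0(out_prefix, "_stratum_summary.csv"),
               estimates = paste0(out_prefix, "_estimates.csv"),
               log = paste0(out_prefix, "_run.log"))
    utils::write.csv(aug, paths[["participants"]], row.names = FALSE, na = "")
    if (!is.null(fit$ps_fit))
      jsonlite::write_json(
        list(selected_covariates = fit$ps_fit$selected_covariates,
             intercept = fit$ps_fit$intercept,
             coefficients = as.list(fit$ps_fit$coefficients),
             aic = fit$ps_fit$aic,
             ps_vs_response_p = ps_cmp$p_value),
        paths[["model"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(balance, paths[["balance"]], row.names = FALSE)
    utils::write.csv(fit$stratum_summary, paths[["strata"]], row.names = FALSE)
    utils::write.csv(format_estimates(est, digits), paths[["estimates"]],
                     row.names = FALSE)
    if (!is.null(cmp)) {
      paths <- c(paths, comparison = paste0(out_prefix, "_comparison.csv"))
      tab <- rbind(cbind(fit$overall_estimates, arm = "PSS"),
                   cbind(cmp$overall_estimates, arm = "no_PSS"))
      utils::write.csv(format_estimates(tab, digits), paths[["comparison"]],
                       row.names = FALSE)
    }
    note("report written under ", out_prefix)
    log_lines <- c(paste0("pssprev ",
                          as.character(utils::packageVersion("pssprev")),
                          " | R ", R.version.string, " | seed ", seed,
                          " | k ", k, " | B ", B, " | m ", m),
                   log_lines)
    writeLines(log_lines, paths[["log"]])
  }
  out <- fit
  out$balance <- balance
  out$ps_comparison <- ps_cmp
  out$no_pss <- cmp
  out$survey <- survey
  out$paths <- paths
  out$seed <- seed
  invisible(out)
}
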