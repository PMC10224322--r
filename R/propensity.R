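# Non-response propensity model and MNAR diagnostics.

# Backward elimination by AIC, deterministic: starting from the full
# candidate set, repeatedly delete the single term whose removal lowers AIC
# the most, until no deletion lowers AIC. `fit_fun(terms)` must return a
# fitted object for which stats::AIC works, or signal an error.
backward_aic <- function(fit_fun, terms) {
  current <- fit_fun(terms)
  repeat {
    if (length(terms) == 0) break
    aics <- vapply(seq_along(terms), function(i) {
      f <- try(fit_fun(terms[-i]), silent = TRUE)
      if (inherits(f, "try-error")) Inf else stats::AIC(f)
    }, 0)
    best <- which.min(aics)   # first minimum wins on ties
    if (aics[best] < stats::AIC(current)) {
      terms <- terms[-best]
      current <- fit_fun(terms)
    } else break
  }
  list(fit = current, terms = terms)
}

phase2_records <- function(dataset) {
  if (inherits(dataset, "pss_survey")) dataset <- dataset$records
  dataset[dataset$phase == "phase2", , drop = FALSE]
}

#' Fit the non-response propensity model
#'
#' Logistic regression of the phase-II non-response indicator on the
#' candidate covariates, followed by backward elimination under AIC. The
#' propensity score of a subject is the fitted probability of being a
#' non-responder.
#'
#' @param dataset a \code{pss_survey} or participant data.frame.
#' @param candidate_covariates covariate names to start from; default all
#'   six (age, education, PADL, IADL, MMSE, MoCA).
#' @param stepwise if FALSE, keep the full candidate set (used e.g. for
#'   coefficient-recovery studies).
#' @return object of class \code{ps_model_fit}: selected covariates,
#'   intercept, coefficients, AIC and the per-subject propensity scores
#'   \code{ps} (aligned with the phase-II rows, ids in \code{id}).
#' @export
fit_ps_model <- function(dataset, candidate_covariates = COVARIATES,
                         stepwise = TRUE) {
  d <- phase2_records(dataset)
  if (nrow(d) == 0) stop("no phase-II subjects")
  miss <- candidate_covariates[!candidate_covariates %in% names(d)]
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(d[, candidate_covariates]))
    stop("missing covariate values among phase-II subjects")
  y <- as.integer(!d$responded)   # 1 = non-responder
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least 2 responders and 2 non-responders to fit the ",
         "propensity model")
  dd <- d[, candidate_covariates, drop = FALSE]
  dd$.y <- y
  fit_fun <- function(terms) {
    f <- if (length(terms)) stats::reformulate(terms, ".y") else .y ~ 1
    withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = dd),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          fit0 <- suppressWarnings(
            stats::glm(f, family = stats::binomial(), data = dd))
          cf0 <- stats::coef(fit0)[terms]
          cf0[is.na(cf0)] <- 0
          z <- abs(cf0) * apply(dd[, terms, drop = FALSE], 2, stats::sd)
          stop("quasi-complete separation in the propensity model, ",
               "likely driven by covariate '", names(which.max(z)), "'")
        }
        invokeRestart("muffleWarning")
      })
  }
  res <- if (stepwise) backward_aic(fit_fun, candidate_covariates)
         else list(fit = fit_fun(candidate_covariates),
                   terms = candidate_covariates)
  cf <- stats::coef(res$fit)
  intercept <- unname(cf["(Intercept)"])
  coefs <- cf[setdiff(names(cf), "(Intercept)")]
  lp <- intercept +
    if (length(coefs)) as.vector(as.matrix(dd[, names(coefs), drop = FALSE]) %*% coefs)
    else rep(0, nrow(dd))
  structure(list(selected_covariates = res$terms,
                 intercept = intercept,
                 coefficients = coefs,
                 aic = stats::AIC(res$fit),
                 vcov = stats::vcov(res$fit),
                 ps = stats::plogis(lp),
                 id = d$id,
                 responded = d$responded,
                 n = nrow(d)),
            class = "ps_model_fit")
}

#' @export
print.ps_model_fit <- function(x, ...) {
  cat("Non-response propensity model (logistic, backward-AIC)\n")
  cat("  n =", x$n, " AIC =", round(x$aic, 1), "\n")
  cat("  logit(PS) =", round(x$intercept, 3))
  for (nm in names(x$coefficients))
    cat(sprintf(" %+0.3f*%s", x$coefficients[[nm]], nm))
  cat("\n")
  invisible(x)
}

#' Predict propensity scores for new subjects
#'
#' @param model a \code{ps_model_fit}.
#' @param covariates data.frame containing every selected covariate.
#' @return numeric vector of scores in (0, 1).
#' @export
predict_ps <- function(model, covariates) {
  stopifnot(inherits(model, "ps_model_fit"))
  need <- names(model$coefficients)
  miss <- need[!need %in% names(covariates)]
  if (length(miss)) stop("covariates required by the propensity model are ",
                         "missing: ", paste(miss, collapse = ", "))
  lp <- model$intercept +
    if (length(need)) as.vector(as.matrix(covariates[, need, drop = FALSE]) %*%
                                model$coefficients)
    else rep(0, nrow(covariates))
  stats::plogis(lp)
}

#' Covariate balance between responders and non-responders
#'
#' For each covariate: group means and SDs, a standardized mean difference
#' (absolute mean difference over the pooled SD \eqn{\sqrt{(s_1^2+s_2^2)/2}}),
#' and a two-sample p-value. The test is Welch's t when both groups pass a
#' Shapiro-Wilk normality pre-check (on at most \code{max_shapiro}
#' subsampled values each), and the Wilcoxon rank-sum test otherwise.
#'
#' @param dataset a \code{pss_survey} or participant data.frame.
#' @param covariates covariate names to tabulate.
#' @param test "auto" (normality pre-check), "t" or "wilcoxon".
#' @param alpha significance level of the normality pre-check.
#' @param max_shapiro subsample cap for the Shapiro-Wilk check.
#' @return data.frame with one row per covariate; the \code{degenerate}
#'   column flags zero pooled SD (SMD reported as 0).
#' @export
balance_table <- function(dataset, covariates = COVARIATES, test = "auto",
                          alpha = 0.05, max_shapiro = 5000) {
  d <- phase2_records(dataset)
  g1 <- d[d$responded %in% TRUE, , drop = FALSE]
  g0 <- d[d$responded %in% FALSE, , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g0) == 0)
    stop("both responders and non-responders are required")
  rows <- lapply(covariates, function(v) {
    x1 <- g1[[v]]; x0 <- g0[[v]]
    m1 <- mean(x1); m0 <- mean(x0)
    s1 <- stats::sd(x1); s0 <- stats::sd(x0)
    pooled <- sqrt((s1^2 + s0^2) / 2)
    degenerate <- !is.finite(pooled) || pooled == 0
    smd <- if (degenerate) 0 else abs(m1 - m0) / pooled
    if (degenerate) {
      warning("zero pooled SD for '", v, "'; SMD reported as 0")
      pv <- NA_real_; used <- "none"
    } else {
      used <- test
      if (test == "auto") {
        normal_ok <- function(x) {
          x <- if (length(x) > max_shapiro) sample(x, max_shapiro) else x
          if (length(unique(x)) < 3) return(FALSE)
          stats::shapiro.test(x)$p.value > alpha
        }
        used <- if (normal_ok(x1) && normal_ok(x0)) "t" else "wilcoxon"
      }
      pv <- if (used == "t") stats::t.test(x1, x0)$p.value
            else stats::wilcox.test(x1, x0, exact = FALSE)$p.value
    }
    data.frame(covariate = v, mean_responders = m1, sd_responders = s1,
               mean_nonresponders = m0, sd_nonresponders = s0,
               smd = smd, test = used, p_value = pv,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare propensity-score distributions of responders and non-responders
#'
#' Wilcoxon rank-sum test of the fitted PS between the two response groups.
#' Under MNAR the non-responders sit higher; under MAR-given-nothing the
#' model has no signal and the test is null-calibrated.
#'
#' @param model a \code{ps_model_fit}.
#' @param dataset optional; defaults to the data the model was fitted on
#'   (response status is stored in the fit).
#' @return list with the rank-sum statistic, p-value, group means/medians
#'   and which group is higher.
#' @export
compare_ps_distributions <- function(model, dataset = NULL) {
  stopifnot(inherits(model, "ps_model_fit"))
  resp <- model$responded
  ps <- model$ps
  if (!is.null(dataset)) {
    d <- phase2_records(dataset)
    ps <- predict_ps(model, d)
    resp <- d$responded
  }
  p1 <- ps[resp %in% TRUE]; p0 <- ps[resp %in% FALSE]
  if (length(p1) == 0 || length(p0) == 0)
    stop("both response groups must be non-empty")
  wt <- stats::wilcox.test(p0, p1, exact = FALSE)
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       mean_responders = mean(p1),
       mean_nonresponders = mean(p0),
       median_responders = stats::median(p1),
       median_nonresponders = stats::median(p0),
       higher_group = if (mean(p0) >= mean(p1)) "nonresponders" else "responders")
}
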