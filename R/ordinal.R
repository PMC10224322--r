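# Proportional-odds outcome model used by the regression (RE) and
# multiple-imputation (REMI) estimators. Parameterisation follows polr:
# logit P(Y <= k) = zeta_k - x'beta, with Y ordered
# normal < mci < dementia.

#' Fit the stratum-level ordinal outcome model
#'
#' Proportional-odds logistic regression of the three-level diagnosis on the
#' candidate covariates, fitted on responders by maximum likelihood, with
#' the same backward-AIC elimination as the propensity model. When the
#' responders of a stratum exhibit only two diagnosis categories the model
#' degenerates to a binomial logistic regression with a single cutpoint
#' (the absent category gets probability zero); a single observed category
#' raises a \code{pssprev_degenerate} error so callers can fall back to
#' simple estimation.
#'
#' @param responders data.frame of responders with a \code{diagnosis}
#'   column in \code{c("normal","mci","dementia")} and covariate columns.
#' @param candidate_covariates covariates to start from.
#' @param stepwise if FALSE, keep the full candidate set.
#' @return object of class \code{ordinal_fit}: observed \code{levels},
#'   \code{coefficients} (beta), \code{zeta} (cutpoints), joint \code{vcov}
#'   over c(beta, zeta), \code{aic}, selected covariates and \code{n}.
#' @export
fit_ordinal_model <- function(responders, candidate_covariates = COVARIATES,
                              stepwise = TRUE) {
  d <- responders
  if (!nrow(d)) stop_degenerate("no responders to fit the outcome model on")
  if (anyNA(d[, candidate_covariates])) stop("missing covariate values")
  y <- factor(d$diagnosis, levels = STATUS_LEVELS, ordered = TRUE)
  if (anyNA(y)) stop("diagnosis outside {normal, mci, dementia}")
  obs <- STATUS_LEVELS[STATUS_LEVELS %in% unique(as.character(y))]
  if (length(obs) < 2)
    stop_degenerate("responders show a single diagnosis category ('",
                    obs, "')")
  dd <- d[, candidate_covariates, drop = FALSE]
  if (length(obs) == 3) {
    dd$.y <- droplevels(y)
    fit_fun <- function(terms) {
      f <- if (length(terms)) stats::reformulate(terms, ".y") else .y ~ 1
      fit <- suppressWarnings(MASS::polr(f, data = dd, Hess = TRUE))
      if (!fit$convergence == 0) stop("polr did not converge")
      fit
    }
    res <- try(
      if (stepwise) backward_aic(fit_fun, candidate_covariates)
      else list(fit = fit_fun(candidate_covariates),
                terms = candidate_covariates),
      silent = TRUE)
    if (inherits(res, "try-error"))
      stop_degenerate("proportional-odds fit failed: ",
                      attr(res, "condition")$message)
    fit <- res$fit
    beta <- fit$coefficients
    zeta <- fit$zeta
    V <- try(stats::vcov(fit), silent = TRUE)
    if (inherits(V, "try-error"))
      stop_degenerate("singular Hessian in the proportional-odds fit")
    aic <- stats::AIC(fit)
  } else {
    # two observed categories: binomial glm mapped to the polr scale
    dd$.y <- as.integer(as.character(y) == obs[2])
    fit_fun <- function(terms) {
      f <- if (length(terms)) stats::reformulate(terms, ".y") else .y ~ 1
      suppressWarnings(stats::glm(f, family = stats::binomial(), data = dd))
    }
    res <- if (stepwise) backward_aic(fit_fun, candidate_covariates)
           else list(fit = fit_fun(candidate_covariates),
                     terms = candidate_covariates)
    cf <- stats::coef(res$fit)
    beta <- cf[setdiff(names(cf), "(Intercept)")]
    zeta <- c(-unname(cf["(Intercept)"]))
    # P(Y = obs[2]) = plogis(a + x'b)  <=>  logit P(Y <= obs[1]) = -a - x'b
    Vg <- stats::vcov(res$fit)
    # reorder to c(beta, zeta) and flip the intercept's sign
    J <- diag(length(cf))
    rownames(J) <- colnames(J) <- names(cf)
    ord <- c(setdiff(names(cf), "(Intercept)"), "(Intercept)")
    V <- (J %*% Vg %*% t(J))[ord, ord, drop = FALSE]
    V[, "(Intercept)"] <- -V[, "(Intercept)"]
    V["(Intercept)", ] <- -V["(Intercept)", ]
    aic <- stats::AIC(res$fit)
  }
  names(zeta) <- paste0("zeta", seq_along(zeta))
  structure(list(levels = obs,
                 coefficients = beta,
                 zeta = zeta,
                 vcov = V,
                 aic = aic,
                 selected_covariates = res$terms,
                 n = nrow(d)),
            class = "ordinal_fit")
}

stop_degenerate <- function(...) {
  stop(structure(class = c("pssprev_degenerate", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Predicted category probabilities from an ordinal fit
#'
#' @param fit an \code{ordinal_fit}.
#' @param newdata data.frame with the selected covariates.
#' @param params optional replacement parameter vector c(beta, zeta), e.g. a
#'   posterior draw; defaults to the MLE.
#' @return matrix n x 3 with columns normal, mci, dementia summing to 1.
#' @export
predict_ordinal_probs <- function(fit, newdata, params = NULL) {
  stopifnot(inherits(fit, "ordinal_fit"))
  nb <- length(fit$coefficients)
  if (is.null(params)) {
    beta <- fit$coefficients
    zeta <- fit$zeta
  } else {
    beta <- params[seq_len(nb)]
    zeta <- sort(params[nb + seq_along(fit$zeta)])  # keep cutpoints ordered
  }
  n <- nrow(newdata)
  eta <- if (nb) as.vector(
    as.matrix(newdata[, names(fit$coefficients), drop = FALSE]) %*% beta)
  else rep(0, n)
  cum <- vapply(zeta, function(z) stats::plogis(z - eta), numeric(n))
  cum <- matrix(cum, nrow = n)
  cum <- cbind(0, cum, 1)
  probs_obs <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  out <- matrix(0, n, 3, dimnames = list(NULL, STATUS_LEVELS))
  out[, fit$levels] <- probs_obs
  out
}

#' Single stochastic imputation of missing diagnoses
#'
#' Draws one parameter vector from the large-sample posterior approximation
#' N(MLE, vcov), computes each non-responder's category probabilities under
#' that draw, and samples one diagnosis each — the proper-imputation step of
#' the REMI estimator.
#'
#' @param fit an \code{ordinal_fit} with a valid variance matrix.
#' @param nonresponders data.frame of subjects to impute.
#' @return character vector of imputed diagnoses.
#' @export
impute_once <- function(fit, nonresponders) {
  stopifnot(inherits(fit, "ordinal_fit"))
  n <- nrow(nonresponders)
  if (n == 0) return(character(0))
  mle <- c(fit$coefficients, fit$zeta)
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("variance matrix of the ordinal fit is not positive semi-definite; ",
         "the stratum is too small or the fit too unstable for imputation — ",
         "consider fewer strata")
  draw <- if (max(abs(V)) < 1e-12) mle else
    as.vector(MASS::mvrnorm(1, mu = mle, Sigma = V, tol = 1e-6))
  pr <- predict_ordinal_probs(fit, nonresponders, params = draw)
  u <- stats::runif(n)
  cum <- t(apply(pr, 1, cumsum))
  STATUS_LEVELS[1L + (u > cum[, 1]) + (u > cum[, 2])]
}
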