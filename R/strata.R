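# Equal-size propensity-score stratification.

#' Partition subjects into equal-count propensity-score strata
#'
#' Subjects are ranked by propensity score (ties broken by stable input
#' order) and cut into \code{k} consecutive blocks whose sizes differ by at
#' most one; blocks with the extra subject come first. Rank-based blocks —
#' rather than value-based quantile cuts with interpolation — guarantee the
#' equal-size contract even with tied scores.
#'
#' @param ps numeric vector of propensity scores.
#' @param k number of strata (default 5, the classic quintile
#'   subclassification; k = 1 yields the unstratified analysis arm).
#' @return object of class \code{stratum_assignment}: \code{k},
#'   \code{boundaries} (the largest PS in each of strata 1..k-1),
#'   \code{stratum_of} (index 1..k per subject, input order) and
#'   \code{sizes}.
#' @examples
#' a <- assign_strata(runif(23), k = 5)
#' a$sizes
#' @export
assign_strata <- function(ps, k = 5) {
  n <- length(ps)
  stopifnot(k >= 1)
  if (k > n) stop("cannot form ", k, " strata from ", n, " subjects")
  if (anyNA(ps)) stop("propensity scores contain NA")
  if (n > 1 && stats::sd(ps) == 0)
    warning("constant propensity scores: stratification is uninformative")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(ps)                       # radix sort: stable for ties
  stratum_of <- integer(n)
  stratum_of[ord] <- rep(seq_len(k), times = sizes)
  boundaries <- if (k > 1) sort(ps)[cumsum(sizes)[-k]] else numeric(0)
  structure(list(k = k, boundaries = boundaries, stratum_of = stratum_of,
                 sizes = sizes),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("PS stratification: k =", x$k, " sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  if (length(x$boundaries))
    cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-stratum composition summary
#'
#' Counts and fractions of each diagnosis state (normal / MCI / dementia /
#' missing) among all subjects of each stratum, responder counts, and
#' covariate means.
#'
#' @param assignment a \code{stratum_assignment} over the phase-II subjects.
#' @param dataset a \code{pss_survey} or participant data.frame; its
#'   phase-II rows must align with the assignment.
#' @param covariates covariate columns to average.
#' @return data.frame, one row per stratum.
#' @export
stratum_summary <- function(assignment, dataset, covariates = COVARIATES) {
  stopifnot(inherits(assignment, "stratum_assignment"))
  d <- phase2_records(dataset)
  if (nrow(d) != length(assignment$stratum_of))
    stop("assignment does not match the phase-II subjects of the dataset")
  states <- c(STATUS_LEVELS, "missing")
  rows <- lapply(seq_len(assignment$k), function(s) {
    ds <- d[assignment$stratum_of == s, , drop = FALSE]
    n <- nrow(ds)
    cnt <- vapply(states, function(x) sum(ds$diagnosis == x), 0L)
    out <- data.frame(stratum = s, n = n, n_responders = sum(ds$responded))
    for (x in states) {
      out[[paste0("n_", x)]] <- cnt[[x]]
      out[[paste0("frac_", x)]] <- if (n > 0) cnt[[x]] / n else NA_real_
    }
    for (v in covariates) out[[paste0("mean_", v)]] <- mean(ds[[v]])
    out
  })
  do.call(rbind, rows)
}
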