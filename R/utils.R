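#' @keywords internal
"_PACKAGE"

# Canonical covariate order used throughout the package.
COVARIATES <- c("age", "education", "padl", "iadl", "mmse", "moca")

# Diagnosis categories in increasing severity; "missing" is a data state,
# not a category.
STATUS_LEVELS <- c("normal", "mci", "dementia")

#' Round half away from zero
#'
#' Presentation rounding for report tables (base \code{round} rounds half to
#' even, which does not match conventional table formatting).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a prevalence estimate record
#'
#' @param category outcome category ("normal", "mci" or "dementia").
#' @param scope estimate scope: a stratum label, "phase2" or "overall".
#' @param method "SE", "RE", "REMI" or "complete_case".
#' @param point point estimate in percent.
#' @param sd standard deviation in percent (NA when not computed).
#' @param n_basis number of subjects underlying the estimate.
#' @param fallback TRUE when a degenerate model forced a fallback to SE.
#' @return one-row data.frame with a 95\% normal CI clipped to [0, 100].
#' @export
prevalence_estimate <- function(category, scope, method, point, sd,
                                n_basis, fallback = FALSE) {
  stopifnot(point >= -1e-8, point <= 100 + 1e-8)
  point <- min(max(point, 0), 100)
  lo <- if (is.na(sd)) NA_real_ else max(0, point - 1.96 * sd)
  hi <- if (is.na(sd)) NA_real_ else min(100, point + 1.96 * sd)
  data.frame(category = category, scope = scope, method = method,
             point = point, sd = sd, ci_lo = lo, ci_hi = hi,
             n_basis = n_basis, fallback = fallback,
             stringsAsFactors = FALSE)
}

# Derive reproducible per-stage seeds from one master seed so that, e.g.,
# changing the number of imputations does not perturb the generator stream.
# Offsets are fixed per stage; results stay within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, covariates = 103L, status = 107L,
               screen = 109L, nonresponse = 113L, ps = 127L,
               impute = 131L, bootstrap = 137L, pipeline = 139L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stage]]
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
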