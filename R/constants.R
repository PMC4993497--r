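#' Default model constants
#'
#' One versioned table of the fixed constants used by the allometric and
#' covalent-index parameterisation and by the infection scenarios. All
#' parameterisation functions accept a `constants` argument so refitted
#' coefficients (e.g. from [fit_absorption_regression()]) can replace the
#' published ones without touching call sites.
#'
#' @details The entries are:
#' \describe{
#'   \item{q_liver}{Liver blood flow limiting the effective ventilation rate,
#'     L/g/d (default 99.14e-3).}
#'   \item{vr_coef}{Coefficient of the maximal ventilation rate allometry,
#'     L/g/d at 1 kg body weight (default 254.4e-3).}
#'   \item{allometry}{Allometric exponent for metabolic scaling of
#'     ventilation and elimination with body weight (default -1/4).}
#'   \item{p_slope, p_intercept}{Logit-scale regression of absorption
#'     efficiency on the covalent index (defaults 0.18, -2.31).}
#'   \item{ke0_slope, ke0_intercept}{Log-scale regression of the
#'     weight-corrected elimination rate on the covalent index
#'     (defaults 0.25, -1.78).}
#'   \item{log_base}{Base of the logarithms in the two QSAR regressions;
#'     10 by convention, settable to `exp(1)` for sensitivity checks.}
#'   \item{infection_uptake, infection_elimination}{Factors by which
#'     infection changes host uptake (via absorption efficiency) and
#'     elimination in the Cd-like mode (defaults 2 and 1.7; the Co-like
#'     mode uses their reciprocals).}
#' }
#'
#' @return A named list of class `biodyn_constants`.
#' @export
#' @examples
#' cst <- default_constants()
#' cst$q_liver
default_constants <- function() {
  structure(list(
    q_liver        = 99.14e-3,   # L/g/d
    vr_coef        = 254.4e-3,   # L/g/d at 1 kg
    allometry      = -0.25,
    p_slope        = 0.18,
    p_intercept    = -2.31,
    ke0_slope      = 0.25,
    ke0_intercept  = -1.78,
    log_base       = 10,
    infection_uptake      = 2,
    infection_elimination = 1.7
  ), class = "biodyn_constants")
}

.constant_names <- function() names(default_constants())

#' Validate and complete a constants table
#'
#' Fills missing entries with defaults; unknown keys are rejected.
#'
#' @param constants A named list (possibly partial) of model constants.
#' @return A complete `biodyn_constants` list.
#' @export
as_constants <- function(constants = NULL) {
  base <- default_constants()
  if (is.null(constants)) return(base)
  stopifnot(is.list(constants))
  unknown <- setdiff(names(constants), names(base))
  if (length(unknown) > 0L)
    stop("unknown constant(s): ", paste(unknown, collapse = ", "))
  for (nm in names(constants)) {
    v <- constants[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("constant '", nm, "' must be a single finite number")
    base[[nm]] <- v
  }
  base
}

#' @export
print.biodyn_constants <- function(x, ...) {
  cat("Biodynamic model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
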