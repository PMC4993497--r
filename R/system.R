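#' Kinetic parameter bundle
#'
#' The rate constants of the one-compartment mass balance: dissolved uptake
#' `ku` (L/g/d), elimination `ke` (1/d), host relative growth `g` (1/d,
#' growth dilution) and parasite uptake `kp` (1/d; 0 for uninfected fish).
#' The total loss rate `ke + g + kp` appearing in denominators must be
#' positive.
#'
#' @param ku Dissolved uptake rate constant, L/g/d, >= 0.
#' @param ke Elimination rate constant, 1/d, >= 0.
#' @param g Host relative growth rate constant, 1/d (may be negative, e.g.
#'   weight loss, so long as `ke + g + kp > 0`).
#' @param kp Parasite uptake rate constant, 1/d, >= 0.
#' @param derived_from Optional provenance list recording how `ku`/`ke` were
#'   parameterised: fields `p` (absorption efficiency, fraction in (0,1)),
#'   `vr` (ventilation rate, L/g/d), `ke0` (weight-corrected elimination,
#'   1/d), `covalent_index`, `weight_g`. When present, `ku` must equal
#'   `p * vr` within tolerance.
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(ku = 0.005, ke = 0.02, g = 0.015)
kinetic_params <- function(ku, ke, g = 0, kp = 0, derived_from = NULL) {
  for (v in list(ku, ke, g, kp))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate constants must be single finite numbers")
  if (ku < 0) stop("ku must be >= 0")
  if (ke < 0) stop("ke must be >= 0")
  if (kp < 0) stop("kp must be >= 0")
  if (ke + g + kp <= 0)
    stop("degenerate loss: total loss rate ke + g + kp must be > 0")
  if (!is.null(derived_from)) {
    need <- c("p", "vr")
    if (!all(need %in% names(derived_from)))
      stop("provenance must carry at least 'p' and 'vr'")
    p <- derived_from$p
    if (p <= 0 || p >= 1)
      stop("absorption efficiency p must lie in (0, 1)")
    if (abs(ku - p * derived_from$vr) > 1e-8 * max(1, ku))
      stop("inconsistent provenance: ku != p * vr")
  }
  structure(list(ku = ku, ke = ke, g = g, kp = kp,
                 derived_from = derived_from),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: ku = %g L/g/d, ke = %g 1/d, g = %g 1/d, kp = %g 1/d\n",
    x$ku, x$ke, x$g, x$kp))
  if (!is.null(x$derived_from)) {
    d <- x$derived_from
    cat(sprintf("  derived from: p = %.4g, VR = %.4g L/g/d", d$p, d$vr))
    if (!is.null(d$covalent_index))
      cat(sprintf(", covalent index = %g", d$covalent_index))
    if (!is.null(d$weight_g)) cat(sprintf(", W = %g g", d$weight_g))
    cat("\n")
  }
  invisible(x)
}

#' Initial state of the fish host
#'
#' @param C0 Initial whole-fish metal concentration, ug/g wet weight, >= 0.
#' @param W0 Initial whole-fish wet weight, g, > 0.
#' @return An object of class `fish_state`.
#' @export
fish_state <- function(C0, W0) {
  if (!is.finite(C0) || C0 < 0) stop("C0 must be finite and >= 0")
  if (!is.finite(W0) || W0 <= 0) stop("W0 must be finite and > 0")
  structure(list(C0 = as.numeric(C0), W0 = as.numeric(W0)),
            class = "fish_state")
}

#' Parasite load of an infected fish
#'
#' @param np Number of parasite individuals, >= 1.
#' @param Wp0 Total initial parasite wet weight, g, > 0.
#' @param gp Parasite relative growth rate constant, 1/d.
#' @param Cp0 Initial parasite metal concentration, ug/g ww, >= 0.
#' @return An object of class `parasite_load`.
#' @export
parasite_load <- function(np, Wp0, gp, Cp0 = 0) {
  if (!is.finite(np) || np < 1) stop("np must be >= 1 for an infected system")
  if (!is.finite(Wp0) || Wp0 <= 0) stop("invalid load: Wp0 must be > 0")
  if (!is.finite(gp)) stop("gp must be finite")
  if (!is.finite(Cp0) || Cp0 < 0) stop("Cp0 must be >= 0")
  structure(list(np = as.numeric(np), Wp0 = as.numeric(Wp0),
                 gp = as.numeric(gp), Cp0 = as.numeric(Cp0)),
            class = "parasite_load")
}

#' Host-parasite system
#'
#' Combines the fish host's initial state with an optional parasite load.
#'
#' @param fish A [fish_state()].
#' @param load A [parasite_load()], or `NULL` for an uninfected fish.
#' @return An object of class `host_parasite_system`.
#' @export
#' @examples
#' sys <- host_parasite_system(fish_state(C0 = 0.05, W0 = 10),
#'                             parasite_load(np = 6, Wp0 = 0.011,
#'                                           gp = 0.021, Cp0 = 0.4))
host_parasite_system <- function(fish, load = NULL) {
  stopifnot(inherits(fish, "fish_state"))
  if (!is.null(load)) stopifnot(inherits(load, "parasite_load"))
  structure(list(fish = fish, load = load), class = "host_parasite_system")
}

#' @export
print.host_parasite_system <- function(x, ...) {
  cat(sprintf("Host: C0 = %g ug/g ww, W0 = %g g\n", x$fish$C0, x$fish$W0))
  if (is.null(x$load)) {
    cat("Uninfected (no parasite load)\n")
  } else {
    cat(sprintf(
      "Parasites: np = %g, Wp0 = %g g, gp = %g 1/d, Cp0 = %g ug/g ww\n",
      x$load$np, x$load$Wp0, x$load$gp, x$load$Cp0))
  }
  invisible(x)
}

#' Prediction series container
#'
#' Time-stamped predicted concentrations for the host and (optionally) the
#' parasite compartment. Behaves as a data frame with columns `time_d`,
#' `host_conc_ugg` and, for infected runs, `parasite_conc_ugg`.
#'
#' @param times Evaluation times, days.
#' @param host_conc Host whole-body concentrations, ug/g ww.
#' @param parasite_conc Optional parasite concentrations, ug/g ww.
#' @return A data frame of class `prediction_series`.
#' @export
prediction_series <- function(times, host_conc, parasite_conc = NULL) {
  stopifnot(length(times) == length(host_conc))
  df <- data.frame(time_d = as.numeric(times),
                   host_conc_ugg = as.numeric(host_conc))
  if (!is.null(parasite_conc)) {
    stopifnot(length(parasite_conc) == length(times))
    df$parasite_conc_ugg <- as.numeric(parasite_conc)
  }
  class(df) <- c("prediction_series", "data.frame")
  df
}

#' Write a prediction series to CSV
#'
#' @param series A [prediction_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a prediction series from CSV
#'
#' @param path CSV path with columns `time_d`, `host_conc_ugg` and
#'   optionally `parasite_conc_ugg`.
#' @return A [prediction_series()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_d", "host_conc_ugg") %in% names(df)))
    stop("schema error in ", path,
         ": need columns 'time_d' and 'host_conc_ugg'")
  prediction_series(df$time_d, df$host_conc_ugg, df$parasite_conc_ugg)
}
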