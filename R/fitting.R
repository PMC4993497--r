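#' Project body weight from a relative growth rate
#'
#' Discrete daily compounding growth law `Wt = W0 * (1 + g)^t`.
#'
#' @param W0 Initial wet weight, g, > 0.
#' @param g_rate Relative growth rate constant, 1/d, with `1 + g_rate > 0`.
#' @param t Time, days.
#' @return Projected weight, g.
#' @export
#' @examples
#' project_weight(10, 0.015, 36)
project_weight <- function(W0, g_rate, t) {
  if (any(W0 <= 0)) stop("invalid argument: W0 must be > 0")
  if (any(1 + g_rate <= 0)) stop("invalid argument: 1 + g_rate must be > 0")
  W0 * (1 + g_rate)^t
}

#' Fit a relative growth rate to a weight time series
#'
#' Least-squares calibration of the growth law `Wt = W0 * (1 + g)^t`
#' against measured weights, the procedure used for both the fish host and
#' the parasite individuals. The optimisation is a deterministic bounded
#' one-dimensional minimisation over `g` in (-0.5, 1.0) 1/d.
#'
#' @param times Measurement times, days, increasing.
#' @param weights Measured wet weights, g, > 0.
#' @param fit_w0 If `FALSE` (default) `W0` is fixed to the first
#'   observation; if `TRUE`, `W0` is profiled out by closed-form linear
#'   least squares at each candidate `g`.
#' @param scale Residual scale: `"linear"` (default, weights as measured) or
#'   `"log"` (residuals of log weights).
#' @return A list of class `growth_fit`: `estimate` (1/d), `w0`,
#'   `objective` (residual sum of squares), `residuals`, `settings`.
#' @export
#' @examples
#' t <- seq(0, 36, by = 6)
#' fit_growth_rate(t, project_weight(10, 0.015, t))$estimate
fit_growth_rate <- function(times, weights, fit_w0 = FALSE,
                            scale = c("linear", "log")) {
  scale <- match.arg(scale)
  times <- as.numeric(times); weights <- as.numeric(weights)
  if (length(times) < 2L || length(weights) != length(times))
    stop("degenerate series: need >= 2 aligned time points")
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("degenerate series: weights must be finite and > 0")

  obj <- function(g) {
    x <- (1 + g)^times
    w0 <- if (fit_w0) {
      if (scale == "log") exp(mean(log(weights) - times * log1p(g)))
      else sum(weights * x) / sum(x * x)
    } else {
      weights[1] / x[1]
    }
    pred <- w0 * x
    if (scale == "log") sum((log(weights) - log(pred))^2)
    else sum((weights - pred)^2)
  }
  opt <- stats::optimize(obj, interval = c(-0.5, 1.0), tol = 1e-10)
  g_hat <- opt$minimum
  x <- (1 + g_hat)^times
  w0_hat <- if (fit_w0) {
    if (scale == "log") exp(mean(log(weights) - times * log1p(g_hat)))
    else sum(weights * x) / sum(x * x)
  } else weights[1] / x[1]
  pred <- w0_hat * x
  structure(list(
    estimate = g_hat,
    w0 = w0_hat,
    objective = opt$objective,
    residuals = weights - pred,
    fitted = pred,
    settings = list(fit_w0 = fit_w0, scale = scale,
                    bracket = c(-0.5, 1.0), tol = 1e-10)
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: g = %.6g 1/d (W0 = %.4g g, RSS = %.4g)\n",
              x$estimate, x$w0, x$objective))
  invisible(x)
}

#' Whole-fish concentration from muscle concentration
#'
#' Linear conversion `C_whole = slope * C_muscle + intercept`, used when a
#' literature study reports muscle concentrations only. The coefficients
#' come from user-supplied muscle-to-whole-body regressions and are never
#' built in.
#'
#' @param muscle_conc Muscle concentration, ug/g.
#' @param slope,intercept Regression coefficients of the linear map.
#' @return Whole-fish concentration, ug/g.
#' @export
whole_fish_from_muscle <- function(muscle_conc, slope, intercept = 0) {
  if (!is.finite(slope)) stop("slope must be finite")
  slope * muscle_conc + intercept
}

#' Fit the parasite uptake rate constant
#'
#' Calibrates `kp` in the parasite balance `dCp/dt = kp * Cf - np * gp * Cp`
#' against observed parasite concentrations, with the host-derived source
#' `Cf` held piecewise constant per interval. The analytical solution is
#' linear in `kp`, so the least-squares estimate is closed form:
#' writing `Cp(t; kp) = A(t) + kp * B(t)` with `A` the decay of the initial
#' concentration and `B` the unit-uptake response, the estimate is
#' `kp = sum(B * (Cp_obs - A)) / sum(B^2)`, clipped at zero.
#'
#' @param times Observation times, days.
#' @param cp_obs Observed parasite concentrations, ug/g ww.
#' @param cf_schedule An [exposure_schedule()] whose concentrations are the
#'   per-interval host source values `Cf` (ug/g ww).
#' @param np Number of parasite individuals.
#' @param gp Parasite relative growth rate constant, 1/d.
#' @param Cp0 Initial parasite concentration, ug/g ww.
#' @param parasite_loss As in [simulate_infected()].
#' @return A list of class `kp_fit`: `estimate` (1/d, >= 0), `objective`,
#'   `residuals`, `fitted`, `settings`.
#' @export
fit_parasite_uptake_rate <- function(times, cp_obs, cf_schedule, np, gp,
                                     Cp0 = 0,
                                     parasite_loss = c("np_gp", "gp")) {
  parasite_loss <- match.arg(parasite_loss)
  stopifnot(inherits(cf_schedule, "exposure_schedule"))
  times <- as.numeric(times); cp_obs <- as.numeric(cp_obs)
  if (length(times) < 2L || length(cp_obs) != length(times))
    stop("need >= 2 aligned parasite concentration observations")
  lambda_p <- if (parasite_loss == "np_gp") np * gp else gp
  if (lambda_p <= 0) stop("degenerate loss: np * gp must be > 0")

  A <- .piecewise_solution(
    exposure_schedule(cf_schedule$times, rep(0, length(cf_schedule$times)),
                      cf_schedule$horizon),
    Cp0, lambda_p, 0, times)
  B <- .piecewise_solution(cf_schedule, 0, lambda_p, 1, times)

  if (all(B == 0)) {
    if (any(cp_obs - A > 1e-12))
      warning("unidentifiable: zero forcing but nonzero observed accumulation")
    kp <- 0
  } else {
    kp <- sum(B * (cp_obs - A)) / sum(B * B)
    if (kp < 0) {
      warning("negative kp estimate clipped to 0 ",
              "(parasite uptake cannot be negative)")
      kp <- 0
    }
  }
  fitted <- A + kp * B
  structure(list(
    estimate = kp,
    objective = sum((cp_obs - fitted)^2),
    residuals = cp_obs - fitted,
    fitted = fitted,
    settings = list(np = np, gp = gp, Cp0 = Cp0,
                    parasite_loss = parasite_loss)
  ), class = "kp_fit")
}

#' @export
print.kp_fit <- function(x, ...) {
  cat(sprintf("Parasite uptake fit: kp = %.6g 1/d (RSS = %.4g)\n",
              x$estimate, x$objective))
  invisible(x)
}

#' Jointly refit uptake and elimination rate constants
#'
#' Least-squares calibration of `(ku, ke)` in the uninfected host model
#' against an observed concentration time series under a known exposure
#' schedule, with the growth rate held fixed. Optimised on the log scale
#' (both constants are positive) by Nelder-Mead.
#'
#' @param schedule An [exposure_schedule()].
#' @param times Observation times, days.
#' @param conc_obs Observed host concentrations, ug/g ww.
#' @param C0 Initial host concentration, ug/g ww.
#' @param g Known growth rate constant, 1/d.
#' @param start Named start values `c(ku = ..., ke = ...)`; defaults to a
#'   crude moment-based guess.
#' @return A list of class `kinetics_fit`: `ku`, `ke`, `objective`,
#'   `residuals`, `convergence`.
#' @export
fit_uptake_elimination <- function(schedule, times, conc_obs, C0 = 0, g = 0,
                                   start = NULL) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  times <- as.numeric(times); conc_obs <- as.numeric(conc_obs)
  if (length(times) < 3L || length(conc_obs) != length(times))
    stop("need >= 3 aligned observations to identify two rate constants")
  if (is.null(start)) {
    cw_bar <- mean(schedule$conc)
    ke0 <- 0.05
    ku0 <- max(max(conc_obs), 1e-8) * (ke0 + g) / max(cw_bar, 1e-8)
    start <- c(ku = ku0, ke = ke0)
  }
  obj <- function(theta) {
    ku <- exp(theta[1]); ke <- exp(theta[2])
    if (ke + g <= 0) return(1e12)
    pred <- .piecewise_solution(schedule, C0, ke + g, ku, times)
    sum((conc_obs - pred)^2)
  }
  opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  ku <- exp(opt$par[1]); ke <- exp(opt$par[2])
  pred <- .piecewise_solution(schedule, C0, ke + g, ku, times)
  structure(list(
    ku = unname(ku), ke = unname(ke),
    objective = opt$value,
    residuals = conc_obs - pred,
    fitted = pred,
    convergence = opt$convergence
  ), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Kinetics fit: ku = %.6g L/g/d, ke = %.6g 1/d (RSS = %.4g)\n",
              x$ku, x$ke, x$objective))
  invisible(x)
}
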