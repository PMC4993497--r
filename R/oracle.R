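#' Fixed-step 4th-order numerical oracle
#'
#' Integrates the differential form of the mass balance(s) —
#' `dCt/dt = ku * Cw_i - (ke + g + kp) * Ct` and, for infected systems,
#' `dCp/dt = kp * Ct * W/Wp - np * gp * Cp` — with the classical 4th-order
#' Runge-Kutta scheme at a fixed step, under the same piecewise-constant
#' water forcing as the analytical engines. Serves as the independent
#' verification oracle for [simulate_uninfected()] and
#' [simulate_infected()].
#'
#' Unlike the analytical parasite solution, the oracle feeds the parasite
#' compartment with the *continuous* host concentration, so the analytical
#' coupled solution (which holds the host-derived forcing constant within
#' each renewal interval) converges to the oracle only as the interval
#' length shrinks (first order in interval length).
#'
#' @details Within an interval the forcing is constant, so the RK4 one-step
#' map is affine with constant coefficients; the implementation composes
#' that affine map exactly (binary powering), which reproduces the RK4
#' iterates in closed form and keeps fine-step runs fast.
#'
#' @param schedule An [exposure_schedule()].
#' @param params A [kinetic_params()].
#' @param system A [host_parasite_system()]; an uninfected system (no load)
#'   integrates the host equation alone.
#' @param eval_times Evaluation times (days).
#' @param step Integration step, days, > 0.
#' @param parasite_loss As in [simulate_infected()].
#' @return A [prediction_series()].
#' @export
ode_oracle <- function(schedule, params, system, eval_times, step = 1e-3,
                       parasite_loss = c("np_gp", "gp")) {
  stopifnot(inherits(schedule, "exposure_schedule"),
            inherits(params, "kinetic_params"),
            inherits(system, "host_parasite_system"))
  parasite_loss <- match.arg(parasite_loss)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("invalid argument: step must be > 0")

  load <- system$load
  coupled <- !is.null(load)
  lambda_h <- params$ke + params$g + params$kp

  if (coupled) {
    lambda_p <- if (parasite_loss == "np_gp") load$np * load$gp else load$gp
    ratio <- system$fish$W0 / load$Wp0
    M <- matrix(c(-lambda_h, params$kp * ratio, 0, -lambda_p), 2, 2)
    state <- c(system$fish$C0, load$Cp0)
    forcing <- function(cw) c(params$ku * cw, 0)
  } else {
    M <- matrix(-lambda_h, 1, 1)
    state <- system$fish$C0
    forcing <- function(cw) params$ku * cw
  }
  d <- nrow(M)

  eval_times <- as.numeric(eval_times)
  .interval_index(schedule, eval_times)   # range check
  t0 <- schedule$times[1]
  breaks <- sort(unique(c(t0, schedule$times, schedule$horizon, eval_times)))
  breaks <- breaks[breaks >= t0 - 1e-12]

  out <- matrix(NA_real_, length(eval_times), d)
  record <- function(t, s) {
    hit <- which(abs(eval_times - t) < 1e-9)
    if (length(hit)) out[hit, ] <<- rep(s, each = length(hit))
  }
  record(breaks[1], state)

  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    len <- b - a
    if (len <= 0) next
    cw <- schedule$conc[.interval_index(schedule, a)]
    n <- max(1L, as.integer(ceiling(len / step - 1e-9)))
    h <- len / n
    H <- h * M
    H2 <- H %*% H; H3 <- H2 %*% H; H4 <- H3 %*% H
    A <- diag(d) + H + H2 / 2 + H3 / 6 + H4 / 24
    Bc <- h * (diag(d) + H / 2 + H2 / 6 + H3 / 24)
    bvec <- Bc %*% forcing(cw)
    # homogeneous form, composed n times by binary powering
    P <- rbind(cbind(A, bvec), c(rep(0, d), 1))
    state <- (.mat_pow(P, n) %*% c(state, 1))[seq_len(d)]
    record(b, state)
  }
  if (anyNA(out[, 1]))
    stop("internal error: evaluation time not hit by the integrator grid")
  prediction_series(eval_times, out[, 1],
                    if (coupled) out[, 2] else NULL)
}

.mat_pow <- function(P, n) {
  R <- diag(nrow(P))
  while (n > 0L) {
    if (n %% 2L == 1L) R <- R %*% P
    P <- P %*% P
    n <- n %/% 2L
  }
  R
}
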