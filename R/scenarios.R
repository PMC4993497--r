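#' Infection effect modifiers
#'
#' How parasitism alters host uptake and elimination, based on reported
#' tapeworm-cyprinid kinetics for two reference metals. In the Cd-like mode
#' the infected host takes up metal 2 times faster (acting on the
#' absorption efficiency; ventilation is assumed unaffected) and eliminates
#' it 1.7 times slower; in the Co-like mode uptake is 2 times slower and
#' elimination 1.7 times faster.
#'
#' @param mode `"cd_like"` or `"co_like"`.
#' @param constants Model constants (the base factors 2 and 1.7 live
#'   there), see [default_constants()].
#' @return Named numeric vector `c(uptake = ..., elimination = ...)` of
#'   multiplicative factors applied to the uninfected host's absorption
#'   efficiency and elimination rate.
#' @export
#' @examples
#' infection_modifiers("cd_like")   # uptake x2, elimination /1.7
infection_modifiers <- function(mode, constants = default_constants()) {
  constants <- as_constants(constants)
  u <- constants$infection_uptake
  e <- constants$infection_elimination
  switch(mode,
    cd_like = c(uptake = u, elimination = 1 / e),
    co_like = c(uptake = 1 / u, elimination = e),
    stop("unknown infection mode: ", mode,
         " (expected 'cd_like' or 'co_like')"))
}

#' Build the ten-sensitivity-scenario table
#'
#' The fixed factor-of-2 sensitivity grid: standard scenarios S1/S2 keep
#' default uninfected parameters; A1/A2 halve and B1/B2 double the
#' absorption efficiency; C1/C2 halve and D1/D2 double the elimination
#' rate. Odd-numbered scenarios use the Cd-like infection mode, even the
#' Co-like mode.
#'
#' @return A data frame of class `scenario_table` with columns `name`,
#'   `p_factor`, `ke_factor`, `infection_mode`.
#' @export
build_scenario_table <- function() {
  df <- data.frame(
    name = c("S1", "S2", "A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
    p_factor = c(1, 1, 0.5, 0.5, 2, 2, 1, 1, 1, 1),
    ke_factor = c(1, 1, 1, 1, 1, 1, 0.5, 0.5, 2, 2),
    infection_mode = rep(c("cd_like", "co_like"), 5),
    stringsAsFactors = FALSE)
  class(df) <- c("scenario_table", "data.frame")
  df
}

#' Create a single scenario specification
#'
#' @param name Scenario label.
#' @param p_factor Multiplier on the uninfected absorption efficiency, > 0.
#' @param ke_factor Multiplier on the uninfected elimination rate, > 0.
#' @param infection_mode `"cd_like"` or `"co_like"`.
#' @return A one-row `scenario_table`.
#' @export
scenario_spec <- function(name, p_factor = 1, ke_factor = 1,
                          infection_mode = "cd_like") {
  if (p_factor <= 0 || ke_factor <= 0) stop("scenario factors must be > 0")
  infection_modifiers(infection_mode)   # validates the mode
  df <- data.frame(name = name, p_factor = p_factor, ke_factor = ke_factor,
                   infection_mode = infection_mode, stringsAsFactors = FALSE)
  class(df) <- c("scenario_table", "data.frame")
  df
}

#' Apply a scenario to a base parameter set
#'
#' Produces the uninfected and infected kinetic parameters for one
#' scenario. The `p_factor` acts on the absorption-efficiency fraction
#' (not on `ku` directly), preserving the assumption that ventilation is
#' unaffected; the infected parameters additionally carry the
#' infection-mode modifiers and the base `kp`. Any modified efficiency
#' reaching 1 is capped at `1 - 1e-6` with a warning.
#'
#' @param base A [kinetic_params()] carrying provenance (`p`, `vr`); the
#'   provenance is required whenever an efficiency multiplier differs
#'   from 1.
#' @param spec A one-row [scenario_spec()] / row of
#'   [build_scenario_table()].
#' @param constants Model constants.
#' @return List with elements `uninfected` and `infected`, both
#'   [kinetic_params()].
#' @export
apply_scenario <- function(base, spec, constants = default_constants()) {
  stopifnot(inherits(base, "kinetic_params"))
  constants <- as_constants(constants)
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1L)
    spec <- as.list(spec)
  }
  mods <- infection_modifiers(spec$infection_mode, constants)
  prov <- base$derived_from

  cap_p <- function(p) {
    if (p >= 1) {
      warning("modified absorption efficiency >= 1 capped at 1 - 1e-6")
      p <- 1 - 1e-6
    }
    p
  }

  needs_p <- spec$p_factor != 1 || mods[["uptake"]] != 1
  if (needs_p && is.null(prov))
    stop("base parameters lack provenance (p, VR); cannot apply an ",
         "absorption-efficiency multiplier")

  if (is.null(prov)) {
    ku_u <- base$ku
    prov_u <- NULL
  } else {
    p_u <- cap_p(prov$p * spec$p_factor)
    ku_u <- p_u * prov$vr
    prov_u <- utils::modifyList(prov, list(p = p_u))
  }
  ke_u <- base$ke * spec$ke_factor
  uninfected <- kinetic_params(ku = ku_u, ke = ke_u, g = base$g, kp = 0,
                               derived_from = prov_u)

  p_i <- cap_p(prov_u$p * mods[["uptake"]])
  ku_i <- p_i * prov$vr
  ke_i <- ke_u * mods[["elimination"]]
  infected <- kinetic_params(ku = ku_i, ke = ke_i, g = base$g, kp = base$kp,
                             derived_from = utils::modifyList(
                               prov, list(p = p_i)))
  list(uninfected = uninfected, infected = infected)
}

#' Run the scenario sensitivity sweep
#'
#' Simulates the uninfected fish, the infected fish and the parasites for
#' every scenario, and summarises the spread (max/min ratio across
#' scenarios, grouped into standard vs absorption-efficiency vs
#' elimination scenarios) per compartment and evaluation time.
#'
#' @param schedule An [exposure_schedule()].
#' @param base_params A [kinetic_params()] with provenance and the base
#'   `kp` (held fixed across scenarios).
#' @param system A [host_parasite_system()] with a parasite load.
#' @param specs A [build_scenario_table()] or subset thereof.
#' @param eval_times Evaluation times, days.
#' @param constants Model constants.
#' @param ... Passed to [simulate_infected()].
#' @return A list of class `scenario_sweep`: `results` (per-scenario list
#'   with derived parameters and series), `predictions` (tidy data frame
#'   scenario x compartment x time) and `spread` (per group, compartment
#'   and time the max/min ratio of predictions).
#' @export
run_sweep <- function(schedule, base_params, system, specs = build_scenario_table(),
                      eval_times, constants = default_constants(), ...) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1L)
  if (anyDuplicated(specs$name)) stop("scenario names must be unique")
  constants <- as_constants(constants)

  results <- lapply(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, , drop = FALSE]
    pars <- apply_scenario(base_params, spec, constants)
    uninf <- simulate_uninfected(schedule, pars$uninfected, system$fish,
                                 eval_times)
    inf <- simulate_infected(schedule, pars$infected, system, eval_times, ...)
    list(name = spec$name, spec = spec, params = pars,
         uninfected = uninf, infected = inf)
  })
  names(results) <- specs$name

  predictions <- do.call(rbind, lapply(results, function(r) {
    rbind(
      data.frame(scenario = r$name, compartment = "uninfected_fish",
                 time_d = r$uninfected$time_d,
                 conc_ugg = r$uninfected$host_conc_ugg),
      data.frame(scenario = r$name, compartment = "infected_fish",
                 time_d = r$infected$time_d,
                 conc_ugg = r$infected$host_conc_ugg),
      data.frame(scenario = r$name, compartment = "parasites",
                 time_d = r$infected$time_d,
                 conc_ugg = r$infected$parasite_conc_ugg))
  }))
  rownames(predictions) <- NULL

  group_of <- function(name) {
    first <- substr(name, 1, 1)
    switch(first, S = "standard", A = "absorption", B = "absorption",
           C = "elimination", D = "elimination", "custom")
  }
  predictions$group <- vapply(predictions$scenario, group_of, character(1))

  spread <- do.call(rbind, lapply(
    split(predictions,
          list(predictions$group, predictions$compartment,
               predictions$time_d), drop = TRUE),
    function(d) {
      lo <- min(d$conc_ugg); hi <- max(d$conc_ugg)
      data.frame(group = d$group[1], compartment = d$compartment[1],
                 time_d = d$time_d[1], min_conc = lo, max_conc = hi,
                 spread_ratio = if (lo > 0) hi / lo else NA_real_)
    }))
  rownames(spread) <- NULL
  spread <- spread[order(spread$compartment, spread$time_d, spread$group), ]

  structure(list(results = results, predictions = predictions,
                 spread = spread),
            class = "scenario_sweep")
}

#' @export
print.scenario_sweep <- function(x, ...) {
  cat(sprintf("Scenario sweep: %d scenario(s), %d evaluation time(s)\n",
              length(x$results),
              length(unique(x$predictions$time_d))))
  tmax <- max(x$spread$time_d)
  s <- x$spread[x$spread$time_d == tmax, ]
  cat(sprintf("Terminal (t = %g d) spread ratios (max/min across scenarios):\n",
              tmax))
  print(s[, c("group", "compartment", "spread_ratio")], row.names = FALSE)
  invisible(x)
}

#' Read/write scenario tables as CSV
#'
#' @param path CSV with columns `name`, `p_factor`, `ke_factor`,
#'   `infection_mode`.
#' @return A `scenario_table`.
#' @export
read_scenario_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "p_factor", "ke_factor", "infection_mode")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    scenario_spec(df$name[i], df$p_factor[i], df$ke_factor[i],
                  df$infection_mode[i])))
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' @rdname read_scenario_csv
#' @param specs A `scenario_table`.
#' @export
write_scenario_csv <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE)
  invisible(path)
}
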