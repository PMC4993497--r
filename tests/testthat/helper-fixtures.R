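# Shared fixtures: all generated in code, seeded per test.

# random 12-interval, 36-day renewal schedule (Pb-like fluctuation)
rand_schedule <- function(n_intervals = 12, renewal = 3,
                          range = c(40, 120)) {
  starts <- (seq_len(n_intervals) - 1) * renewal
  exposure_schedule(starts, stats::runif(n_intervals, range[1], range[2]),
                    horizon = n_intervals * renewal)
}

# random plausible kinetic parameters (uninfected unless kp given)
rand_params <- function(kp = 0) {
  kinetic_params(ku = stats::runif(1, 1e-4, 5e-2),
                 ke = stats::runif(1, 5e-3, 0.5),
                 g = stats::runif(1, 0, 0.03),
                 kp = kp)
}

pb_like_params <- function(g = 0.015, kp = 0, weight = 10) {
  derive_kinetic_params(weight, covalent_index = 6.61, g = g, kp = kp)
}

default_system <- function(C0 = 0.05, W0 = 10, np = 6, Wp0 = 0.011,
                           gp = 0.021, Cp0 = 0.4) {
  host_parasite_system(fish_state(C0, W0),
                       parasite_load(np, Wp0, gp, Cp0))
}

# noise-free synthetic rate tables generated exactly from the QSAR relations
qsar_uptake_table <- function(chi, weights,
                              constants = default_constants()) {
  p <- absorption_efficiency(chi, constants)
  data.frame(species = paste0("sp", seq_along(chi)), weight_g = weights,
             metal = paste0("m", seq_along(chi)), covalent_index = chi,
             rate_kind = "uptake",
             rate_value = p * ventilation_rate(weights, constants))
}

qsar_elimination_table <- function(chi, weights,
                                   constants = default_constants()) {
  data.frame(species = paste0("sp", seq_along(chi)), weight_g = weights,
             metal = paste0("m", seq_along(chi)), covalent_index = chi,
             rate_kind = "elimination",
             rate_value = elimination_rate_constant(weights, chi, constants))
}
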