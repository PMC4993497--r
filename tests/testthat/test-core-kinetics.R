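# Analytical engines for the one-compartment mass balance under
# piecewise-constant exposure, and their coupled fish-parasite extension.

test_that("uninfected solution reproduces closed-form hand values", {
  # single interval, accumulation from zero: Ct = (ku Cw / lambda)(1 - e^-lambda t)
  s <- exposure_schedule(0, 100, horizon = 10)
  p <- kinetic_params(ku = 0.01, ke = 0.1, g = 0)
  got <- simulate_uninfected(s, p, fish_state(0, 10), 10)$host_conc_ugg
  expect_equal(got, 10 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(got, 4), 6.3212)

  # pure exponential decay with zero exposure
  s0 <- exposure_schedule(seq(0, 9, 3), rep(0, 4), horizon = 12)
  got0 <- simulate_uninfected(s0, p, fish_state(5, 10), 10)$host_conc_ugg
  expect_equal(got0, 5 * exp(-1), tolerance = 1e-12)

  # constant exposure approaches the steady state ku Cw / (ke + g)
  slong <- exposure_schedule(0, 80, horizon = 500)
  plong <- kinetic_params(ku = 0.005, ke = 0.04, g = 0.01)
  got_ss <- simulate_uninfected(slong, plong, fish_state(0, 10),
                                500)$host_conc_ugg
  expect_equal(got_ss, steady_state(plong, 80), tolerance = 1e-8)
})

test_that("interval recurrence and expanded-sum form agree on random schedules", {
  set.seed(101)
  for (i in 1:100) {
    s <- rand_schedule(n_intervals = sample(3:15, 1),
                       renewal = runif(1, 1, 5))
    p <- rand_params()
    C0 <- runif(1, 0, 2)
    tt <- sort(runif(8, s$times[1], s$horizon))
    lam <- p$ke + p$g
    a <- biodynfish:::.piecewise_solution(s, C0, lam, p$ku, tt)
    b <- biodynfish:::.expanded_solution(s, C0, lam, p$ku, tt)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("analytical host solution matches the RK4 oracle", {
  set.seed(202)
  for (i in 1:20) {
    s <- rand_schedule()
    p <- rand_params()
    fish <- fish_state(runif(1, 0, 1), runif(1, 5, 20))
    tt <- sort(runif(6, 0.5, s$horizon))
    a <- simulate_uninfected(s, p, fish, tt)$host_conc_ugg
    o <- ode_oracle(s, p, host_parasite_system(fish), tt,
                    step = 1e-3)$host_conc_ugg
    expect_lt(max(abs(a - o) / pmax(o, 1e-10)), 1e-5)
  }
})

test_that("infected host with kp = 0 reduces exactly to the uninfected solution", {
  set.seed(303)
  s <- rand_schedule()
  sys <- default_system()
  p0 <- rand_params(kp = 0)
  tt <- seq(1, 36, by = 2.5)
  inf <- simulate_infected(s, p0, sys, tt)
  uninf <- simulate_uninfected(s, p0, sys$fish, tt)
  expect_equal(inf$host_conc_ugg, uninf$host_conc_ugg, tolerance = 1e-12)

  # and with zero initial parasite concentration and no uptake the
  # parasites stay at zero
  sys0 <- host_parasite_system(sys$fish,
                               parasite_load(6, 0.011, 0.021, Cp0 = 0))
  expect_true(all(simulate_infected(s, p0, sys0, tt)$parasite_conc_ugg == 0))
})

test_that("parasite compartment approaches its steady state under constant forcing", {
  # constant water over many renewal intervals, host near equilibrium:
  # Cp -> kp Cf / (np gp)
  s <- exposure_schedule(seq(0, 1990, by = 10), rep(100, 200),
                         horizon = 2000)
  p <- kinetic_params(ku = 0.005, ke = 0.2, g = 0.01, kp = 1.36e-3)
  sys <- default_system(C0 = 0, Cp0 = 0)
  ser <- simulate_infected(s, p, sys, c(1500, 2000))
  ct_ss <- steady_state(p, 100)
  cf_ss <- host_source_concentration(ct_ss, sys$fish$W0, sys$load$Wp0)
  cp_expect <- p$kp * cf_ss / (sys$load$np * sys$load$gp)
  expect_equal(ser$parasite_conc_ugg[2], cp_expect, tolerance = 1e-6)
})

test_that("host_source_concentration is the weight-ratio rescaling", {
  expect_equal(host_source_concentration(2, 10, 0.01), 2000)
  expect_equal(host_source_concentration(0, 3, 0.2), 0)
  expect_equal(host_source_concentration(1.7, 5, 5), 1.7)
  expect_error(host_source_concentration(1, -1, 0.1), "invalid argument")
  expect_error(host_source_concentration(1, 1, 0), "invalid argument")
})

test_that("steady_state has the closed form and its symmetries", {
  p <- kinetic_params(ku = 0.005, ke = 0.04, g = 0.01, kp = 0)
  expect_equal(steady_state(p, 100), 10)
  expect_equal(steady_state(p, 0), 0)
  p2 <- kinetic_params(ku = 0.01, ke = 0.04, g = 0.01, kp = 0)
  expect_equal(steady_state(p2, 100), 2 * steady_state(p, 100))
})

test_that("Ct is monotone in ku and Cw, and antitone in ke", {
  set.seed(404)
  for (i in 1:10) {
    s <- rand_schedule()
    p <- rand_params()
    fish <- fish_state(0.1, 10)
    tt <- seq(3, 36, by = 3)
    base <- simulate_uninfected(s, p, fish, tt)$host_conc_ugg

    p_up <- kinetic_params(p$ku * 1.5, p$ke, p$g)
    expect_true(all(simulate_uninfected(s, p_up, fish, tt)$host_conc_ugg
                    >= base))

    s_up <- exposure_schedule(s$times, s$conc * 1.2, s$horizon)
    expect_true(all(simulate_uninfected(s_up, p, fish, tt)$host_conc_ugg
                    >= base))

    p_ke <- kinetic_params(p$ku, p$ke * 1.5, p$g)
    expect_true(all(simulate_uninfected(s, p_ke, fish, tt)$host_conc_ugg
                    <= base))
  }
})

test_that("all outputs are nonnegative for nonnegative inputs", {
  set.seed(505)
  for (i in 1:10) {
    s <- rand_schedule()
    p <- rand_params(kp = runif(1, 0, 5e-3))
    sys <- default_system(C0 = runif(1, 0, 1), Cp0 = runif(1, 0, 1))
    tt <- seq(0, 36, by = 4)
    ser <- simulate_infected(s, p, sys, tt)
    expect_true(all(ser$host_conc_ugg >= 0))
    expect_true(all(ser$parasite_conc_ugg >= 0))
  }
})

test_that("degenerate and out-of-range inputs raise the documented errors", {
  s <- rand_schedule()
  expect_error(kinetic_params(0.01, 0, g = 0), "degenerate loss")
  expect_error(kinetic_params(0.01, 0.05, g = -0.1), "degenerate loss")
  p <- kinetic_params(0.01, 0.05)
  expect_error(simulate_uninfected(s, p, fish_state(0, 10), 40),
               "outside the exposure horizon")
  expect_error(simulate_uninfected(s, p, fish_state(0, 10), -1),
               "outside the exposure horizon")
  expect_error(parasite_load(6, -0.01, 0.021), "invalid load")
  sys <- host_parasite_system(fish_state(0, 10),
                              parasite_load(6, 0.011, gp = 0))
  expect_error(simulate_infected(s, p, sys, 10), "degenerate loss")
  expect_error(ode_oracle(s, p, host_parasite_system(fish_state(0, 10)),
                          10, step = 0), "invalid argument")
  # params with kp > 0 are rejected by the uninfected engine
  expect_error(simulate_uninfected(s, kinetic_params(0.01, 0.05, kp = 1e-3),
                                   fish_state(0, 10), 10), "kp")
})

test_that("evaluation at a renewal time belongs to the interval starting there", {
  # two intervals with a concentration jump at t = 3: evaluating at 3 must
  # use the new interval's concentration in the forcing term going forward,
  # and equal the left limit (continuity of C), while an instant later the
  # slopes differ
  s <- exposure_schedule(c(0, 3), c(100, 0), horizon = 6)
  p <- kinetic_params(0.01, 0.1, 0)
  f <- fish_state(0, 10)
  at3 <- simulate_uninfected(s, p, f, 3)$host_conc_ugg
  expect_equal(at3, 10 * (1 - exp(-0.3)), tolerance = 1e-12)
  # just after 3 the solution decays (new interval Cw = 0)
  just_after <- simulate_uninfected(s, p, f, 3.01)$host_conc_ugg
  expect_lt(just_after, at3)
})

test_that("refining a schedule leaves the host solution unchanged", {
  set.seed(606)
  s <- rand_schedule()
  p <- rand_params()
  f <- fish_state(0.2, 12)
  tt <- seq(1, 36, by = 5)
  a <- simulate_uninfected(s, p, f, tt)$host_conc_ugg
  b <- simulate_uninfected(refine_schedule(s, 3), p, f, tt)$host_conc_ugg
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("analytical parasite series converges first-order to the coupled oracle", {
  set.seed(707)
  s <- rand_schedule()
  p <- pb_like_params(kp = 1.36e-3)
  sys <- default_system()
  tt <- c(9, 18, 27, 36)
  oracle <- ode_oracle(s, p, sys, tt, step = 1e-3)$parasite_conc_ugg
  errs <- sapply(c(1, 2, 4), function(f) {
    x <- simulate_infected(refine_schedule(s, f), p, sys,
                           tt)$parasite_conc_ugg
    max(abs(x - oracle) / oracle)
  })
  expect_lt(errs[2], errs[1] / 1.9)
  expect_lt(errs[3], errs[2] / 1.9)
})

test_that("midpoint and interval-mean forcing options are more accurate than start", {
  set.seed(808)
  s <- rand_schedule()
  p <- pb_like_params(kp = 1.36e-3)
  sys <- default_system()
  tt <- c(12, 24, 36)
  oracle <- ode_oracle(s, p, sys, tt, step = 1e-3)$parasite_conc_ugg
  err <- function(fs) {
    x <- simulate_infected(s, p, sys, tt,
                           forcing_sample = fs)$parasite_conc_ugg
    max(abs(x - oracle) / oracle)
  }
  expect_lt(err("midpoint"), err("start"))
  expect_lt(err("mean"), err("start"))
})
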