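# Allometric ventilation, covalent-index QSAR relations, and the
# regression refits that recover them from literature rate tables.

test_that("ventilation allometry matches hand evaluations", {
  expect_equal(vr_max(10), 0.2544 * 0.01^(-0.25), tolerance = 1e-12)
  expect_equal(vr_max(10), 0.80448, tolerance = 1e-5)
  expect_equal(vr_max(1000), 0.2544, tolerance = 1e-12)   # 1 kg reference
  # halving the weight scales VRmax by 2^(1/4)
  expect_equal(vr_max(5) / vr_max(10), 2^0.25, tolerance = 1e-12)

  expect_equal(ventilation_rate(10),
               0.09914 * vr_max(10) / (0.09914 + vr_max(10)),
               tolerance = 1e-12)
  expect_equal(ventilation_rate(10), 0.08826, tolerance = 1e-4)
  # liver limitation: VR < min(Q_liver, VRmax) for any weight
  for (w in c(0.1, 1, 10, 100, 1e4)) {
    expect_lt(ventilation_rate(w), min(0.09914, vr_max(w)))
  }
  # saturation: tiny fish (VRmax huge) -> VR -> Q_liver;
  # huge fish (VRmax small) -> VR -> VRmax
  expect_equal(ventilation_rate(1e-9), 0.09914, tolerance = 1e-3)
  expect_equal(ventilation_rate(1e20) / vr_max(1e20), 1, tolerance = 1e-3)
  expect_error(vr_max(0), "invalid argument")
  expect_error(ventilation_rate(-5), "invalid argument")
})

test_that("absorption efficiency is the inverse logit of the QSAR relation", {
  p0 <- 10^-2.31 / (1 + 10^-2.31)
  expect_equal(absorption_efficiency(0), p0, tolerance = 1e-12)
  expect_equal(absorption_efficiency(0), 0.004875, tolerance = 5e-4)
  expect_equal(absorption_efficiency(6), 10^-1.23 / (1 + 10^-1.23),
               tolerance = 1e-12)
  expect_equal(absorption_efficiency(6), 0.05561, tolerance = 1e-4)
  # logistic limits and range
  expect_gt(absorption_efficiency(200), 1 - 1e-10)
  expect_lt(absorption_efficiency(-200), 1e-10)
  chis <- seq(-50, 50, by = 2.5)
  p <- absorption_efficiency(chis)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))
})

test_that("elimination QSAR and allometry match hand evaluations", {
  expect_equal(weight_corrected_elimination(0), 10^-1.78, tolerance = 1e-12)
  expect_equal(weight_corrected_elimination(0), 0.01660, tolerance = 5e-4)
  expect_equal(weight_corrected_elimination(6), 10^-0.28, tolerance = 1e-12)
  expect_equal(elimination_rate_constant(10, 0), 10^-1.78 * 10^-0.25,
               tolerance = 1e-12)
  expect_equal(elimination_rate_constant(1, 3.3),
               weight_corrected_elimination(3.3), tolerance = 1e-12)
  expect_equal(elimination_rate_constant(20, 3.3) /
                 elimination_rate_constant(10, 3.3), 2^-0.25,
               tolerance = 1e-12)
  # strictly increasing in the covalent index
  expect_true(all(diff(weight_corrected_elimination(seq(0, 10, 0.5))) > 0))
})

test_that("uptake rate constant composes efficiency and ventilation", {
  expect_equal(uptake_rate_constant(10, 0),
               absorption_efficiency(0) * ventilation_rate(10),
               tolerance = 1e-12)
  expect_equal(uptake_rate_constant(10, 0), 4.303e-4, tolerance = 1e-3)
  # ku < VR always (p < 1)
  set.seed(11)
  w <- runif(20, 1, 500); chi <- runif(20, 0, 12)
  expect_true(all(uptake_rate_constant(w, chi) < ventilation_rate(w)))
})

test_that("logit round-trip recovers the linear predictor to 1e-10", {
  set.seed(12)
  for (i in 1:25) {
    w <- runif(1, 1, 200); chi <- runif(1, -2, 12)
    p <- uptake_rate_constant(w, chi) / ventilation_rate(w)
    expect_equal(log10(p / (1 - p)), 0.18 * chi - 2.31, tolerance = 1e-10)
  }
})

test_that("derive_kinetic_params bundles rates with consistent provenance", {
  par <- derive_kinetic_params(10, 6.61, g = 0.015, kp = 1.36e-3)
  expect_s3_class(par, "kinetic_params")
  expect_equal(par$ku, par$derived_from$p * par$derived_from$vr,
               tolerance = 1e-12)
  expect_equal(par$ke,
               elimination_rate_constant(10, 6.61), tolerance = 1e-12)
  expect_equal(par$g, 0.015)
  expect_equal(par$kp, 1.36e-3)
})

test_that("noise-free QSAR tables are refitted to the generating coefficients", {
  chi <- seq(0.5, 10, length.out = 12)
  w <- seq(2, 120, length.out = 12)
  fu <- fit_absorption_regression(qsar_uptake_table(chi, w))
  expect_equal(fu$slope, 0.18, tolerance = 1e-7)
  expect_equal(fu$intercept, -2.31, tolerance = 1e-7)
  expect_equal(fu$r2, 1, tolerance = 1e-9)
  expect_equal(fu$n, 12)

  fe <- fit_elimination_regression(qsar_elimination_table(chi, w))
  expect_equal(fe$slope, 0.25, tolerance = 1e-7)
  expect_equal(fe$intercept, -1.78, tolerance = 1e-7)
  expect_equal(fe$r2, 1, tolerance = 1e-9)
})

test_that("weight correction removes allometry for a single metal", {
  # one metal, many weights, exact quarter-power data: ke0 constant
  w <- c(1, 5, 20, 80, 300)
  tab <- qsar_elimination_table(rep(4, 5), w)
  ke0 <- tab$rate_value * w^0.25
  expect_equal(max(ke0) - min(ke0), 0, tolerance = 1e-12)
})

test_that("refits are permutation invariant and reject degenerate designs", {
  chi <- c(1, 3, 5, 7, 9)
  w <- c(5, 10, 20, 40, 80)
  tab <- qsar_uptake_table(chi, w)
  set.seed(13)
  shuffled <- tab[sample(nrow(tab)), ]
  f1 <- fit_absorption_regression(tab)
  f2 <- fit_absorption_regression(shuffled)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)

  expect_error(fit_absorption_regression(qsar_uptake_table(rep(3, 5), w)),
               "share one covalent index")
  expect_error(fit_absorption_regression(tab[1:2, ]), "insufficient data")
})

test_that("records with implied efficiency outside (0,1) are excluded with a warning", {
  chi <- c(1, 3, 5, 7, 9)
  w <- c(5, 10, 20, 40, 80)
  tab <- qsar_uptake_table(chi, w)
  # inflate one uptake rate beyond the ventilation rate -> implied p > 1
  tab$rate_value[3] <- ventilation_rate(tab$weight_g[3]) * 1.5
  expect_warning(f <- fit_absorption_regression(tab), "excluded")
  expect_equal(f$n, 4)
})

test_that("logit-scale noise leaves the refit unbiased over replicates", {
  set.seed(14)
  chi <- seq(1, 9, length.out = 8)
  w <- seq(5, 100, length.out = 8)
  vr <- ventilation_rate(w)
  ests <- t(replicate(500, {
    y <- 0.18 * chi - 2.31 + rnorm(8, 0, 0.15)
    p <- 10^y / (1 + 10^y)
    tab <- data.frame(weight_g = w, covalent_index = chi,
                      rate_kind = "uptake", rate_value = p * vr)
    f <- fit_absorption_regression(tab)
    c(f$slope, f$intercept)
  }))
  # mean estimates within 4 Monte-Carlo standard errors of truth
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 0.18), 4 * se[1])
  expect_lt(abs(mean(ests[, 2]) + 2.31), 4 * se[2])
})

test_that("constants table is validated and the log base is switchable", {
  expect_error(as_constants(list(bogus = 1)), "unknown constant")
  expect_error(as_constants(list(p_slope = "a")), "finite number")
  nat <- as_constants(list(log_base = exp(1)))
  y <- 0.18 * 4 - 2.31
  expect_equal(absorption_efficiency(4, nat), exp(y) / (1 + exp(y)),
               tolerance = 1e-12)
  # refit under natural log recovers the same coefficients it generated
  chi <- seq(1, 9, 2); w <- seq(10, 90, 20)
  p <- exp(0.18 * chi - 2.31) / (1 + exp(0.18 * chi - 2.31))
  tab <- data.frame(weight_g = w, covalent_index = chi,
                    rate_kind = "uptake",
                    rate_value = p * ventilation_rate(w, nat))
  f <- fit_absorption_regression(tab, nat)
  expect_equal(f$slope, 0.18, tolerance = 1e-7)
})
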