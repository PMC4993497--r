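# biodynfish

One-compartment biodynamic (toxicokinetic) modelling of metal accumulation
in fish — and in fish–parasite systems — under fluctuating aqueous exposure
with periodic water renewal.

Intestinal parasites such as acanthocephalans accumulate metals far above
their fish host's levels and alter the host's own uptake kinetics, which
matters to anyone interpreting fish metal burdens in biomonitoring. This
package is for ecotoxicologists who want a mechanistic, low-parameter
alternative to raw parasite/host concentration ratios: a mass-balance model
that can be parameterised from fish weight and metal chemistry alone,
calibrated from time series, and stress-tested against its own assumptions.

## The model

For an uninfected fish the whole-body concentration *C*<sub>t</sub>
(µg/g ww) follows

    dCt/dt = ku·Cw(t) − (ke + g)·Ct

with dissolved uptake *k*<sub>u</sub> (L/g/d), elimination *k*<sub>e</sub>
(1/d) and growth dilution *g* (1/d). In an infected host, parasite uptake
*k*<sub>p</sub> (1/d) is one more efflux, and the parasites (count
*n*<sub>p</sub>, total weight *W*<sub>p</sub>, growth *g*<sub>p</sub>)
follow

    dCp/dt = kp·Cf − np·gp·Cp,   Cf = Ct·W/Wp.

The exposure concentration is piecewise constant between water renewals, so
both balances have exact closed-form solutions, which the engines advance
interval by interval; a fixed-step 4th-order Runge–Kutta integrator
(`ode_oracle()`) serves as an independent numerical check.

Uninfected rate constants are derived from fish weight and the metal's
covalent index χ<sub>m</sub>²r:

    VRmax = 254.4e−3·(1e−3·W)^(−1/4)       (quarter-power allometry)
    VR    = Q_liver·VRmax/(Q_liver+VRmax)  (liver-limited ventilation)
    log10(p/(1−p)) = 0.18·χ − 2.31         (absorption efficiency), ku = p·VR
    log10(ke0)     = 0.25·χ − 1.78,        ke = ke0·W^(−1/4)

Also included: growth-rate and parasite-uptake calibration from time series,
the ten-scenario factor-of-2 sensitivity sweep with Cd-like/Co-like
infection modes, validation statistics (r², p, MAE, RMSE, bioconcentration
factors), a seeded synthetic-data generator emulating a 36-day
chub–acanthocephalan Pb exposure, and a command-line interface
(`inst/exec/biodynfish`).

## Worked example

```r
library(biodynfish)

# 36-day exposure, renewal every 3 days, 80 ug/L dissolved Pb
sched <- exposure_schedule(seq(0, 33, by = 3), rep(80, 12), horizon = 36)

# 10-g chub, Pb-like covalent index 6.61, growing at 0.015 1/d,
# hosting parasites that drain 1.36e-3 1/d
par <- derive_kinetic_params(weight = 10, covalent_index = 6.61,
                             g = 0.015, kp = 1.36e-3)
par
#> Kinetic parameters: ku = 0.00622068 L/g/d, ke = 0.419276 1/d, g = 0.015 1/d, kp = 0.00136 1/d
#>   derived from: p = 0.07048, VR = 0.08826 L/g/d, covalent index = 6.61, W = 10 g

sys <- host_parasite_system(
  fish_state(C0 = 0, W0 = 10),
  parasite_load(np = 6, Wp0 = 0.011, gp = 0.021, Cp0 = 0))

simulate_infected(sched, par, sys, eval_times = c(12, 24, 36))
#>   time_d host_conc_ugg parasite_conc_ugg
#> 1     12      1.136233          6.907336
#> 2     24      1.142330         10.251052
#> 3     36      1.142363         10.998008
```

The host saturates near its steady state ku·Cw/(ke+g+kp) ≈ 1.14 µg/g within
two weeks (Pb-like elimination is fast at this body size), while the
parasites — fed by the host pool rescaled by the ~900-fold weight ratio —
climb towards ~11 µg/g, an order of magnitude above the host, reproducing
the characteristic parasite/host enrichment.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch at the given seed:
it generates the synthetic renewal experiment, checks the analytical
solutions against the Runge–Kutta oracle, refits the growth, uptake,
elimination and parasite-uptake constants from the generated data, runs the
ten-scenario sensitivity sweep, and computes the validation statistics and
terminal parasite/host bioconcentration factor, logging each result to
stderr and writing the JSON report to `--out`.
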