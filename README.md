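# rciburn

Mechanistic simulation of **radiation combined injury (RCI)**: a
superficial thermal burn whose surrounding tissue has also received a
prompt, locally confined dose of ionizing radiation. Combined injuries
heal more slowly and more erratically than either insult alone — depleted
resident immune cells, microvascular damage that delays infiltration from
the bloodstream, pro-inflammatory (M1) macrophage skewing above ~2 Gy,
fibroblast dysfunction and elevated infection risk all interact. The
package is for modellers and analysts who need a tested, scriptable
implementation of these dynamics: it exposes the full ODE system, the
dose-dependent initial conditions, a feasibility-driven parameter-sampling
pipeline and a global sensitivity screen as an R library with a thin CLI.

## The model in brief

Sixteen states across two compartments. At the wound: damage `Dam` and
debris `Deb` (unitless), activated neutrophils `N`, macrophages `M1`/`M2`,
T lymphocytes `L1`/`L2`, fibroblasts `F`, and pathogen `P`. In the
surrounding irradiated tissue: resting neutrophils plus undamaged/damaged
resident monocytes, lymphocytes and fibroblasts. Fluxes are built from an
inhibitory saturation Ω(X; Y, Y∞) = X / (1 + Σ(Yₖ/Yₖ∞)²), a Hill switch
Xⁿ/(X_Hⁿ + Xⁿ) with structural exponent n = 6 for collateral damage, and a
radiation influx factor v(t) = 1 − exp(−γ·DR·t) that models microvascular
shutdown and recovery. M2 activation is additionally inhibited by the
damaged-macrophage pool exactly when DR ≥ 2 Gy (the polarization switch).

Initial conditions: resident populations start at their healed steady
state, split by linear-quadratic survival exp(−αDR − βDR²) per cell type;
a piecewise quadratic maps thermal fluence (J/cm²) to initial damage
(superficial burn ≙ 0.1, superficial partial-thickness ≙ 0.9); pathogen is
seeded at P∞·Dam₀/Dam_max whenever DR > 0.

Because no numeric parameter values are available from the primary
sources, the package ships values generated by its own pipeline: Latin
hypercube sampling over documented ranges, acceptance iff (a) integration
succeeds, (b) debris resolves before damage, (c) the superficial burn
heals in 4.667 ± 0.5 d and the partial-thickness burn in 7.833 ± 0.5 d,
then selection of the *representative set* closest (weighted MSE) to the
cohort's mean trajectory. See `vignettes/rci-burn-model.Rmd` for the full
account.

## Worked example

```r
library(rciburn)

p <- rci_representative_params()          # shipped accepted parameter set
for (DR in c(0, 5, 14)) {
  expo <- rci_exposure(severity = "superficial", DR = DR)
  traj <- simulate_rci(build_initial_state(expo, p), p, expo, horizon = 400)
  d <- traj$derived
  cat(sprintf("DR = %2d Gy: healed at %6.1f h (%.2f d), debris resolved %5.1f h\n",
              DR, d$healing_h, d$healing_h / 24, d$debris_h))
}

fit <- fit_lq(0:10, exp(-0.3481 * 0:10 - 0.0723 * (0:10)^2))
cat(sprintf("LQ fit: alpha = %.4f, beta = %.4f\n", fit$alpha, fit$beta))
```

```
DR =  0 Gy: healed at  110.5 h (4.60 d), debris resolved  32.6 h
DR =  5 Gy: healed at  134.8 h (5.62 d), debris resolved  33.8 h
DR = 14 Gy: healed at  142.0 h (5.92 d), debris resolved  31.6 h
LQ fit: alpha = 0.3481, beta = 0.0723
```

The burn-only wound heals in 4.60 days — inside the superficial-burn
window — and adding local radiation delays healing monotonically with
dose while debris clearance (an innate-immunity readout) barely moves:
the delay comes from damaged resident pools suppressing repair, not from
slower phagocytosis. The lymphocyte survival-curve fit recovers its
generating coefficients to four decimals.

The same operations are scriptable from a shell:

```sh
Rscript inst/cli/rciburn.R sample --n 5000 --seed 1 --out manifest.csv
Rscript inst/cli/rciburn.R representative --manifest manifest.csv --out rep.json
Rscript inst/cli/rciburn.R simulate --scenario scenario.yaml --params rep.json --out out/
```

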