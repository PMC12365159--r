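# pestivol

Pesticide volatilisation fluxes from gas-concentration time series by
inverse dispersion modelling, with surface vapour-pressure dynamics,
Monte-Carlo uncertainty and cumulative-loss bounds.

## What problem this solves

After a pesticide such as chlorothalonil (C8Cl4N2, M = 265.9 g mol⁻¹) is
sprayed on a field, a substantial fraction can volatilise to the atmosphere
over days to weeks. Volatilisation cannot be measured directly; what can be
measured, at 30-min resolution with an online mass spectrometer, is the gas
concentration `C` at a height `z_ref` above the treated field, together with
standard micrometeorology (friction velocity `u*`, Obukhov length `L`, wind
direction, air temperature). This package implements the full inference
chain from those series to the volatilisation flux, the canopy-surface
vapour pressure, and the cumulative loss as a fraction of the applied dose
— for micrometeorologists, exposure modellers and environmental chemists.

## The model

**Inversion.** Superposition over an emitting area gives
`C = D·F + C_bgd`, where `D` (s m⁻¹) is the dispersion coefficient of the
source area at the receptor and `C_bgd` the background concentration; the
flux is retrieved as `F = (C − C_bgd)/D`. `D` is computed with a
semi-analytical solution of the advection-diffusion equation assuming
power-law profiles `u = a z^p`, `K = b z^n` matched two-point to the
Monin-Obukhov similarity profiles; field polygons are decomposed into
upwind strips in the wind frame. Steps with `D` below a floor (calm, wrong
sector) are masked, not zero-filled.

**Aerodynamic gradient.** An independent flux estimate from a multi-height
profile: `F = −u*·C*` with `C* = k ∂C/∂(ln(z−d) − Ψ_H)`.

**Surface scheme.** A big-leaf resistance analogy links flux and surface
concentration, `C(z₀) = C(z_ref) + F·(R_b + R_a)`, with
`R_a = (ln((z_ref−d)/z₀) − Ψ_H)/(k u*)` and
`R_b = 2/(k u*)·(Sc/Pr)^{2/3}`. Ideal-gas conversion gives the surface
vapour pressure, and the availability ratio
`r = p_vap(z₀)/p_sat(T_air)` — the fraction of the surface covered by
transfer-available compound — is tracked daily and fitted with a double
exponential `a₁e^{−k₁t} + a₂e^{−k₂t}`. The fitted `r(t)` drives a modelled
flux used to fill observation gaps (rescaled over a 7-day moving window)
before trapezoidal cumulation into percent of the applied dose.

**Uncertainty.** Every input (roughness length, displacement height, sensor
position, `u*`, `L`, wind direction, `σ_w`, concentrations, background) is
perturbed from its measured distribution and the chain re-run (100 draws by
default); flux bands are per-step percentiles and cumulative bounds are
percentiles over whole cumulative trajectories.

The package also ships PTR-TOF quantification utilities (chlorine
isotope-envelope calculator, 6-peak summing, zero-intercept calibration,
sensitivity and LOD), application-dose assessment from exposed filters, and
a synthetic campaign generator so the whole chain is testable end to end.

## Worked example

```r
library(pestivol)

cfg <- campaign_config(seed = 7)   # 22-day synthetic campaign, 544 g/ha
res <- run_pipeline(cfg, mc = mc_spec(n_draws = 100), seed = 7)

print(res$fit)
#> Double-exponential availability fit
#>   y = 0.0997 exp(-0.709 t) + 0.0811 exp(-0.0146 t)
#>   SEs: a1 0.0074, k1 0.11, a2 0.0034, k2 0.003; n = 17; converged

sprintf("cumulative loss: mean %.1f%% [%.1f%%, %.1f%%] of dose",
        res$summary["mean"], res$summary["p05"], res$summary["p95"])
#> "cumulative loss: mean 13.7% [9.0%, 18.8%] of dose"

max(res$flux$flux, na.rm = TRUE)
#> 34.9   # peak 30-min flux, ng m-2 s-1
```

The fitted fast decay rate (0.71 ± 0.11 day⁻¹) and slow rate
(0.0146 ± 0.003 day⁻¹) recover the generating availability dynamics
(0.61 and 0.012 day⁻¹) within their standard errors, and the Monte-Carlo
5th–95th cumulative band [9.0%, 18.8%] covers the generating truth (13.1%
of the dose). `run_pipeline(cfg, out_dir = "run1")` additionally writes
`flux.csv`, `surface_state.csv`, `availability_fit.json` and
`cumulative_summary.json`, each stamped with the seed and a config hash.
Flux sign convention everywhere: emission positive, deposition negative.

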