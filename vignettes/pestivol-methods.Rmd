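---
title: "Inferring pesticide volatilisation from concentration time series: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pesticide volatilisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestivol)
```

## The inference problem

A semivolatile pesticide applied to a field emits a surface flux
$F$ (ng m$^{-2}$ s$^{-1}$) that cannot be observed directly. What is
observed is the gas concentration $C$ at a reference height above the
field, at 30-min resolution, together with surface-layer
micrometeorology. Under the superposition principle, and assuming no
chemical sources or sinks in the air between the surface and the sensor,

$$C = D \, F + C_{bgd},$$

where $D$ (s m$^{-1}$) is the dispersion coefficient of the emitting area
at the receptor — its inverse $h = D^{-1}$ is the concentration footprint
— and $C_{bgd}$ is the background. Inverting this relation step by step,
$F = D^{-1}(C - C_{bgd})$, is the core of the package. Everything else
supports it: computing $D$ from the geometry and the turbulence state,
cross-checking $F$ with the aerodynamic-gradient method, interpreting $F$
through a canopy resistance scheme, propagating input uncertainty, and
integrating to a cumulative loss.

## Dispersion model

### Power-law profiles

The surface layer is described by Monin–Obukhov similarity. For the
advection–diffusion equation to admit an analytical solution, wind speed
and eddy diffusivity are approximated by power laws in height above the
displacement plane, $u(z') = a z'^p$ and $K(z') = b z'^n$ with
$z' = z - d$. The four constants are obtained by two-point matching of the
similarity profiles

$$u(z') = \frac{u_*}{k}\left[\ln\frac{z'}{z_0} - \Psi_M(z'/L)\right],
\qquad K(z') = \frac{k u_* z'}{\phi_H(z'/L)}$$

at $z_{ref}-d$ and $(z_{ref}-d)/10$. This reproduces the local slope and
magnitude of both profiles across the layer that controls transfer to the
sensor. In stable stratification the wind profile steepens and the fitted
$p$ grows, as it should.

### Stability functions

The source of the resistance scheme cites the integrated stability
corrections without printing a formula, so the package uses the standard
Businger–Dyer forms on the unstable side,
$\Psi_H = 2\ln\!\big((1+x^2)/2\big)$ with $x = (1-16\zeta)^{1/4}$ (and the
matching $\Psi_M$, $\phi_H = (1-16\zeta)^{-1/2}$), and linear forms
$\Psi_{H,M} = -5.2\,\zeta$, $\phi_H = 1 + 5.2\,\zeta$ on the stable side.
Both coefficients are arguments of `psi_h()` / `psi_m()` and can be
changed. $\zeta$ is clamped to $[-5, 2]$ before evaluation: outside that
range the similarity forms are unreliable and resistances become
pathological in calm periods; the clamp bound is also an argument.

### Ground-source kernel and polygon decomposition

For a ground-level, crosswind-homogeneous strip of unit surface flux
extending a fetch $X$ upwind of the receptor, the crosswind-integrated
solution with the power-law profiles has the closed form

$$D(X, z') = \frac{(b\alpha^2/a)^{\nu}}{b\,\alpha\,\Gamma(1-\nu)}
\; c_0^{\nu}\; \Gamma\!\left(-\nu,\; \frac{c_0}{X}\right),
\qquad
\alpha = 2 + p - n,\;\; \nu = \frac{1-n}{\alpha},\;\;
c_0 = \frac{a z'^{\alpha}}{b \alpha^2},$$

obtained by integrating the classical ground line-source kernel over the
fetch; $\Gamma(\cdot,\cdot)$ is the upper incomplete gamma function,
evaluated for its (small, negative) first argument through the recurrence
to `pgamma`. Two properties anchor the implementation and are enforced in
tests: agreement with a brute-force finite-volume solution of
$\partial(u c)/\partial x = \partial_z(K \partial_z c)$ (within 10%,
actual agreement is ~0.1%), and exact mass conservation
$\int u\,c\,dz = X$ at the downwind edge (within 2%).

Field polygons are rotated into the wind frame (meteorological convention:
the wind direction is where the wind comes *from*; $+x$ points upwind) and
intersected with the upwind axis through the receptor. In the default
**strip mode** each polygon contributes $D(t_{far}) - D(t_{near})$ per
intersected interval — exact, with no discretisation, which is appropriate
when the receptor sits tens of metres inside a large source and lateral
dispersion is second order. A **gaussian mode** adds a lateral plume
spread $\sigma_y(x) = x\,\sigma_w/u(z_{ref})$ on an upwind grid growing
geometrically from 0.5 m, for layouts where sources sit off the wind axis.
Per-source contributions are weighted by each polygon's relative emission
strength (`rel_dose`) and always sum to one over emitting sources.

## Flux retrieval

`invert_flux()` is the exact algebraic inverse of the forward relation.
Steps with $D$ below `d_floor` ($10^{-3}$ s m$^{-1}$) are masked rather
than zero-filled, because the inversion variance scales as $1/D$ and calm
or wrong-sector footprints carry no usable information. The background is
a constant mean (plus sd, used by the Monte-Carlo stage) estimated from a
pre-application window; its diurnal variation is neglected, being more
than an order of magnitude below post-application concentrations.

`gradient_flux()` implements the aerodynamic-gradient method: ordinary
least squares of concentration against $\ln(z-d) - \Psi_H$ over the
available levels (no weighting), $C_* = k \cdot$ slope, $F = -u_* C_*$.
With two valid levels the OLS slope collapses to the two-point finite
difference. On synthetic campaigns with a homogeneous source the gradient
and inversion fluxes agree with a regression slope within 15% of unity.
Sign convention everywhere: emission positive, deposition negative; the
flux CSV header states it.

## Surface vapour pressure and availability

The big-leaf resistance scheme gives the canopy-surface concentration
$C(z_0) = C(z_{ref}) + F(R_b + R_a)$, with
$R_a = [\ln((z_{ref}-d)/z_0) - \Psi_H]/(k u_*)$ and
$R_b = 2/(k u_*)\,(Sc/Pr)^{2/3}$. No measured molecular diffusivity exists
for chlorothalonil, so its Schmidt number is estimated from the
water-vapour diffusivity scaled by Graham's law,
$\sqrt{M_{H_2O}/M}$, giving $Sc \approx 2.4$; `schmidt_number()` exposes
every constant. Ideal-gas conversion ($R = 8.314$ J mol$^{-1}$ K$^{-1}$,
$M = 265.911$ g mol$^{-1}$) turns concentrations into vapour pressures,
and the Clausius–Clapeyron curve anchored at
$p_{sat} = 7.6\times10^{-5}$ Pa at 25 °C with activation energy
95 000 J mol$^{-1}$ (and the curve's own fitted constant 8.3) gives the
saturation pressure. Air temperature is used for both pressures, as a
compromise between sunlit canopy-top and shaded soil temperatures.

The availability ratio $r = p_{vap}(z_0)/p_{sat}(T_{air})$ is aggregated
to daily values over a daytime window (09–16 UT by default, configurable)
because nighttime resistances are the noisiest link in the chain, and
fitted with $y = a_1 e^{-k_1 t} + a_2 e^{-k_2 t}$ by Levenberg–Marquardt
nonlinear least squares (`minpack.lm`), with standard errors and
convergence diagnostics always reported; `fix_k2 = 0` gives the plateau
variant $a_1 e^{-k_1 t} + a_2$ used for remaining-content series. The fit
requires at least 8 daily points. `dissipation_budget()` sums independent
first-order pathways (photodegradation, leaf penetration, volatilisation)
for comparison with the fitted fast rate.

The fitted $r(t)$ drives a modelled flux,
$C(z_0) = r(t)\,p_{sat}(T)\,M/(R T_K)\times10^9$ and
$F = (C(z_0)-C(z_{ref}))/(R_a+R_b)$, which is linearly rescaled to the
measured flux over a 7-day moving window (zero-intercept least squares;
windows with under 50% overlap fall back to the nearest fitted window, and
the applied scale is recorded per step) to fill observation gaps.
Cumulation is trapezoidal on the 30-min grid, reported in percent of the
applied dose (1 g ha$^{-1}$ = $10^5$ ng m$^{-2}$).

## Monte-Carlo uncertainty

All inputs are sampled independently: roughness length log-normal
(arithmetic mean 0.0035 m, sd 0.0004 m, converted internally to log-space
parameters), displacement height normal around $2/3$ of the canopy height
(sd 0.03 m), sensor position normal (1, 1, 0.1 m), wind direction normal
(sd 12.5°), and multiplicative 1-σ factors of 14% on $u_*$, $\sigma_w$
and concentrations and 40% on $L$ (applied multiplicatively so the
stability sign is preserved; factors are redrawn while ≤ 0.05, and redraws
are counted). The sensor-position perturbation re-enters the dispersion
geometry, not the concentration. Default 100 draws.

Two sampling modes exist because the error structure matters for
different questions: **step mode** draws a fresh parameter set every
30-min step and is used for per-step flux percentile bands; **trajectory
mode** draws one parameter set per campaign replicate, preserving the
temporal correlation of systematic errors, and is used for cumulative-loss
bounds — percentiles are taken over whole cumulative trajectories, never
by integrating per-step bands. Zero-variance specifications collapse the
bands onto the deterministic flux exactly, and a concentration-only
specification reproduces the delta-method band width, both enforced in
tests.

## The synthetic campaign generator

The generator exists so that every stage of the chain can be exercised,
end to end, without any external data. It emulates a three-week spring
campaign over a treated winter-wheat field: one pre-application background
day; a 544 g ha$^{-1}$ application; a 450 m square field with the receptor
at 1.9 m, 40 m inside the downwind edge; gradient heights 0.63/1.23/2.03 m;
a background of 5.7 ± 2.2 ng m$^{-3}$; 14% multiplicative concentration
noise; and two receptor outages (days 3–4 and 11–14).

The surface availability decays as
$r(t) = 0.18\,[57 e^{-0.61 t} + 43 e^{-0.012 t}]/100$ — an initial
saturation ratio of 0.18 splitting into a fast pool (~16%/day decay,
dissipation-dominated) and a slow pool sustaining emission for weeks. The
truth flux couples this availability to the physics: $C(z_0)$ from
$r\,p_{sat}(T)$, and the flux solves the resistance equation with its own
ambient feedback, $F = (C(z_0) - C_{bgd})/(R_a + R_b + D)$ — the feedback
is linear, so the fixed point is solved exactly rather than iterated.

Meteorology is a smooth solar-driven cycle with multiplicative noise:
$u_*$ between 0.18 (night) and 0.55 m s$^{-1}$ (day), temperature
16 ± 11 °C peaking at 14 h UT, and the Obukhov length cycling from about
−67 m (convective afternoons) to +29 m (stable nights). These defaults
were chosen once so that the generated campaign reproduces the observable
ranges reported for this kind of measurement: $R_a$ within 10–100 and
$R_b$ within 20–400 s m$^{-1}$, midday fluxes peaking above
30 ng m$^{-2}$ s$^{-1}$ the day after application with sustained daily
maxima three weeks later, and post-application concentrations an order of
magnitude above background. A warm spell (midday near 27 °C) is required
for these magnitudes — $p_{sat}$ roughly quadruples per 10 °C — and is
meteorologically realistic for the emulated season.

What the generator does **not** emulate: horizontal heterogeneity of the
source (application exclusion zones, edge effects), advection from
fields with different application dates, rain and wash-off, humidity- or
temperature-dependent instrument sensitivity, and non-Gaussian turbulence
intermittency. Passing tests therefore demonstrate the correctness and
internal consistency of the inference chain under its own assumptions, not
the field accuracy of any particular campaign.

## Numerical choices

* Near-neutral stratification drives the diffusivity exponent $n \to 1$
  and $\nu \to 0$; $n$ is nudged by $10^{-9}$ to keep the incomplete-gamma
  recurrence away from its removable singularity (the cancellation is
  benign at double precision).
* Wind speeds from the matched profile are floored at small positive
  values so extreme stable draws cannot produce non-physical profiles.
* Strip-mode polygon intersections are exact (ray crossings sorted into
  inside intervals); only the gaussian mode discretises, on a geometric
  upwind grid with ≤ 1 m steps near the receptor.
* The double-exponential fit starts from an amplitude split of 55/45 at
  rates 0.5 and 0.01 day$^{-1}$ with non-negativity bounds; non-convergence
  warns with the optimiser's message, never silently.
* Degenerate inputs are errors, not guesses: non-positive $u_*$ or $z_0$,
  receptors below $d + z_0$, fewer than two gradient levels, empty filter
  sets, all-equal calibration references, zero Monte-Carlo draws.

## Problem sizes used by the test suite

The suite validates the dispersion kernel against a 300 × 3000-cell
finite-volume solution, runs 20 seeded 22-day campaigns with 50-draw
trajectory-mode Monte-Carlo for the cumulative coverage property
(the generating truth falls inside the 5–95% band in ≥ 90% of
replicates), 50 replicate availability fits for confidence-interval
coverage, 200 replicate fits for bias, and 2000 replicates for the Welch
test's type-I rate. These sizes were chosen to make the checked
proportions statistically meaningful while keeping the default suite
comfortably runnable on a laptop.

## Known limitations

* The dispersion kernel is crosswind-integrated; strongly skewed or
  meandering flows, and receptors outside large sources, are served only
  by the simplified gaussian lateral mode.
* No deposition or chemistry during transport: the superposition relation
  assumes a conservative tracer between surface and sensor.
* The availability interpretation of $r$ (surface coverage by unbound
  compound) is a hypothesis; the package quantifies its dynamics but
  cannot distinguish surface processes mechanistically.
* Stability-response tuning of the dispersion coefficient against a
  backward Lagrangian stochastic model is not reproduced; validation is
  against the numerical PDE oracle instead.
* Gap-filling assumes the modelled flux captures the diurnal shape within
  each 7-day window up to a scale factor; structural model error inside
  long outages is not represented in the bands.
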