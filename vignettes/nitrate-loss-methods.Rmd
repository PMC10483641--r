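---
title: "Estimating biologically driven nitrate loss from profiler time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biologically driven nitrate loss from profiler time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvmloss)
```

## The inference problem

A moored profiler in a stratified coastal bloom measures nitrate that
varies for three distinct reasons: internal waves heave the whole water
column vertically (tens of metres, peak to trough), horizontal currents
advect lateral nitrate gradients past the mooring, and — the signal of
interest — migrating dinoflagellates consume nitrate below the euphotic
zone. `dvmloss` removes the two physical signals in sequence and then
estimates the biological loss with propagated uncertainties.

**Isopycnal transform.** Tracers ride on density surfaces when heaved by
internal waves, so each profile is re-expressed as a function of potential
density. Linear interpolation onto uniform sigma-theta bins (default
0.02 kg m⁻³) converts a depth–time grid into a density–time grid; the
interpolated depth of each bin, time-averaged, becomes the display and
integration vertical axis. Linear (not spline) interpolation is used
because the nitracline can rise from undetectable to >10 mmol m⁻³ over
2–3 m and splines overshoot there. Weak density inversions are sorted
away; profiles with inversions above 0.05 kg m⁻³ are flagged unusable
rather than silently reordered.

**Water-mass tracking.** Lateral advection is removed by identity, not
filtering: on each isopycnal, cells are labelled by spice in 0.005 kg m⁻³
bins, and cells sharing a label are treated as the same water mass.
Because no TEOS-10 library is a dependency, spice is the linearized,
density-compensated combination `alpha*T + beta*S` with the same
coefficients as the generator's equation of state (alpha = 0.2 kg m⁻³
per °C, beta = 0.78 kg m⁻³ per salinity unit); the formulation and
coefficients are recorded in the output attributes so an alternative can
be substituted. Contiguous occurrences of a label (allowing interruptions
up to 2 grid steps — the record contains gaps and label jitter) collapse
into one *visit* (time median, nitrate mean); consecutive visits give
nitrate observation pairs. Pairs separated by more than 2 days are
discarded because the same-spice-same-parcel assumption degrades with
time, and any visit at or below the nitrate detection limit
(0.5 mmol m⁻³) is refused — an undetectable value carries no rate
information and must never enter a log-space fit.

**Rate estimation and temporal iteration.** Each pair is fitted with
`N(t+Δt) = N(t) e^{rΔt}`, i.e. `r = log(N₂/N₁)/Δt`, with the two-point
delta-method error `σ_r = sqrt((σ₁/N₁)² + (σ₂/N₂)²)/Δt`; series of three
or more visits use the least-squares slope of log N against time. A
pair's rate is an *average over its own interval*, so when rates are
gridded onto the uniform iteration interval δt (default the native 15-min
step) each estimate is assigned to every window its interval covers and
overlapping estimates combine with inverse-variance weights. This matters
in practice: near the detection limit, short-interval pairs have enormous
rate variance, and midpoint-only assignment would let a single such pair
own its window and inject `e^{rδt}` spikes into the iteration. Windows
covered by no pair are linearly interpolated across gaps up to 1 day;
longer gaps are flagged and excluded. Starting from the first usable
observation in each bin, the predicted nitrate is iterated as
`N̂(t+δt) = N̂(t) e^{rδt}`, the loss rate is the temporal differentiation
`ρNO₃ = −ΔN̂/δt` (positive = loss; supply events with r > 0 are retained
in the field), and the cumulative loss `Nloss` is its running integral —
identically `N₀ − N̂(t)`, which the test suite asserts to 10⁻¹⁰.

## Error propagation

The full linear map from pair-level rate errors to gridded rates is kept
per density bin, so the variance of `log N̂(t)` is computed exactly to
first order — including the strong serial correlation that interpolated
windows inherit from their source estimates, which a
window-independence assumption would miss entirely. Two refinements fell
out of validating coverage on zero-uptake synthetic records:

* **Lognormal bias correction.** `E[e^ε] = e^{Var(ε)/2}` for Gaussian
  rate noise, so the iteration multiplies each step by
  `e^{−ΔVar/2}`; without it the predicted nitrate drifts systematically
  high and the drift, being one-signed across bins, dominates the
  depth-integrated error budget.
* **Block-correlated depth integration.** Density bins lying within one
  native vertical grid cell interpolate the *same* profiler samples, so
  their errors are not independent: within such blocks errors are summed
  linearly and only blocks combine in quadrature under the trapezoid
  weights. Treating all bins as independent demonstrably undercovers.

The predicted nitrate is additionally capped at the bin's maximum
observed value: a water mass cannot be predicted to hold more nitrate
than it was ever seen to hold, which prevents exponential runaway through
interpolated positive rates after the deep pool is exhausted.

With these choices, on a no-uptake scenario with internal waves,
advection and realistic sensor noise, the depth-integrated `Nloss` stays
within twice its propagated standard error at well over 90% of time
steps (the acceptance script recomputes this coverage).

## The synthetic ocean

The generator builds the water column in an isopycnal "label" coordinate
(the rest depth of each isopycnal) and only then heaves it, so the
assumption the isopycnal transform inverts is exactly true in the
simulated data. It emulates:

* a tanh pycnocline (24.4–25.7 kg m⁻³, centre 20 m, width 8 m) plus a
  weak uniform gradient (0.008 kg m⁻³ m⁻¹) so isopycnals exist right to
  the surface, as in strongly heated, freshwater-capped bloom conditions;
* a thermocline co-located with the pycnocline (19 → 10 °C) and salinity
  closing a linear equation of state, so temperature is single-valued on
  isopycnals and the nitrate–temperature climatology
  `N = 80.94 − 5.9 T` (valid T < 14 °C) sets the deep nitrate reservoir:
  about 10 mmol m⁻³ at 25 m rising past 20 mmol m⁻³ below 40 m;
* first-mode internal waves (amplitude 10 m at mid-depth, period 6 h),
  giving the observed ~20-m peak-to-trough tracer excursions;
* along-isopycnal advection as a single-period oscillation (18 h) of a
  density-compensated temperature/salinity anomaly, vertically uniform —
  a minimal stand-in, since the real vertical structure of the advective
  field is unknown; nitrate anomalies follow the same parcels, so nitrate
  is exactly conserved within (isopycnal, spice) classes absent uptake;
* a Gaussian chlorophyll layer (half-width 3 m, initial peak 5 mg m⁻³)
  whose centre rests at 4 m by day, descends at 380 μm s⁻¹ from 18:00
  local until the 32-m floor, and returns over the last 2 h of the
  24-h cycle — the solar day is fixed at 06:00–18:00 local with no
  ephemeris;
* Michaelis–Menten nitrate uptake (maximum 6 mmol N m⁻³ d⁻¹,
  half-saturation 0.5 mmol m⁻³) wherever the layer overlaps the
  25–35 m active range, floored so nitrate never goes negative, with the
  realised rate and its cumulative integral recorded exactly before any
  noise; the layer's chlorophyll integral grows by 0.19 mg Chl per
  mmol N taken up;
* diurnal surface PAR (2000 μmol m⁻² s⁻¹ at noon) attenuated by water
  (0.12 m⁻¹) and chlorophyll (0.035 m⁻¹ per mg m⁻³), emitted as three
  identical irradiance channels; backscatter proportional to chlorophyll
  above a dark offset; i.i.d. Gaussian sensor noise per sample (nitrate
  0.3 mmol m⁻³, a typical UV-nitrate precision; chlorophyll
  0.05 mg m⁻³; temperature and salinity 0.005).

What it does **not** emulate — and hence what passing tests cannot show
about real data: no shear or vertical structure in the advective field,
no mixing or diffusion between water masses, no nitrification or other
nitrogen sources, no fluorescence quenching in the forward model (the
correction is exercised on constructed profiles), no gaps or biofouling
drift, and cells pile up against a rigid surface rather than forming the
visible surface slicks of a real red tide.

## Numerical and design choices

* **Day/night and descent trigger** run through a single local-clock
  helper; records start at local noon by default, matching the natural
  anchor for a migration analysis window.
* **Euphotic depth** interpolates log-linearly between grid cells (exact
  for exponential decay) and references the surface value; profiles that
  never fall below 1% return the grid bottom with an `unresolved` flag.
* **Quenching correction** scales dark-corrected backscatter by the
  chlorophyll:backscatter ratio just below the quenched layer, never
  reduces daytime chlorophyll, and refuses profiles whose reference
  particle signal is at sensor-noise level (a ratio of noise to noise
  otherwise inflates chlorophyll where there is none).
* **Despiking** iterates the 5xMAD running-median rule to convergence,
  which makes quality control exactly idempotent.
* **Descent tracking** uses the chlorophyll centroid over cells above the
  profile's 75th percentile, weighted by each bin's depth thickness:
  density bins are unevenly spaced in depth, and an unweighted centroid
  drags the trajectory toward the densely binned pycnocline. Tracking
  starts a few hours after the trigger so the layer has cleared the
  weakly stratified surface layer where isopycnal depth is poorly
  resolved.
* **Loss–biomass correlations** in the pipeline compare daily-averaged
  series: the migrating layer crossing the fixed 0–33 m integration
  boundary injects a diel oscillation into the biomass integral that is
  migration, not growth. The function default remains the native
  resolution.
* **Climatology fitting** regresses count-weighted per-bin mean nitrate
  on temperature-bin centres; a per-bin-mode variant is available since
  a density ridge, not the mean, may be the more robust target in real
  mixed records. Deficits are undefined (flagged, not zero) at or above
  the 14 °C cutoff, and predictions clip at zero.
* **Degenerate inputs** are flagged, not guessed at: profiles with fewer
  than two density samples, bins never observed, windows with more than
  half the depth range missing, constant series in correlations, and
  non-positive chlorophyll increases in the N:Chl ratio all refuse or
  flag rather than return a number.

## Problem sizes

The shipped tests and the acceptance script run the generator at its
native resolution (1 m × 15 min, 100 m) over 2–4-day windows for the
controlled recovery checks and the full 14-day default scenario for the
end-to-end bloom; these sizes give every stage thousands of observation
pairs while keeping the whole suite in the tens of seconds on a single
core.

## Limitations

The estimator inherits the assumptions of the method: water masses are
assumed conserved between reappearances (no mixing correction along the
spice coordinate), the rate field is assumed representable by pairwise
exponential fits interpolated over at most a day, errors are propagated
to first order with Gaussian assumptions, and nothing distinguishes
biological uptake from any other in-parcel nitrate sink. Below the
detection limit the method is blind: losses in water already stripped of
nitrate are not counted, so cumulative loss is a lower bound late in a
bloom. The climatology stage fits whatever samples it is given — with
synthetic data from the early record, with real data a long external
bottle-sample record should be supplied instead.
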