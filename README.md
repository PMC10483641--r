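# dvmloss

Detecting dinoflagellate diel vertical migration (DVM) in moored-profiler
time series and quantifying the subeuphotic-zone nitrate loss it causes.

## The problem

Dense dinoflagellate red tides can form when motile cells swim to the
sunlit surface by day and down to the deep nutrient pool at night. Testing
this in the field requires separating the *biological* decrease of nitrate
at depth from the apparent variability produced by physics: internal waves
heave isopycnals (and every tracer on them) up and down by tens of metres,
and oscillating currents advect lateral nitrate gradients past a mooring.

`dvmloss` implements the full inference chain for high-resolution
profiler records (1-m vertical, ~15-min temporal resolution of
temperature, salinity, density, nitrate, chlorophyll fluorescence,
backscatter and irradiance), for biological oceanographers working on
harmful algal blooms and nutrient budgets:

1. **Sensor preprocessing** — nitrate despiking (running median, 5xMAD)
   and detection-limit flagging, fluorescence quenching correction against
   backscatter, PAR from irradiance channels, euphotic (1% light) depth,
   turbidity proxy.
2. **Isopycnal mapping** — every profile is interpolated onto uniform
   potential-density bins (0.02 kg m⁻³), removing internal-wave heaving;
   fields are plotted and integrated against mean isopycnal depth.
3. **Water-mass tracking** — on each isopycnal, cells are binned by spice
   (0.005 kg m⁻³); points in the same spice bin are the same water mass,
   and its reappearances at the mooring yield nitrate observation pairs.
4. **Nitrate budget** — each pair is fitted with the exponential model
   `N(t+Δt) = N(t) e^{rΔt}`, giving the nitrate-specific rate of change
   r (d⁻¹). Rates are gridded in time, the predicted nitrate is iterated
   over a uniform interval δt, the volumetric loss rate is
   `ρNO₃ = −ΔN̂/δt` (mmol N m⁻³ d⁻¹, positive = loss), and its time
   integral is the cumulative loss `Nloss` (mmol N m⁻³) — all with
   first-order error propagation.
5. **Climatology comparison** — nitrate–temperature probability density
   functions (0.25 °C × 1 mmol m⁻³ bins), a weighted least-squares
   climatological line for T < 14 °C, and the nitrate deficit of bloom
   observations relative to it.
6. **Bloom metrics** — depth-integrated loss/biomass series and their
   correlation, layer descent-speed estimation, and the N:Chl ratio.

A first-class **synthetic-ocean generator** simulates all of these
processes with recorded ground truth (true displacement, migration
trajectory, uptake-rate and cumulative-loss fields), so every stage of the
chain can be scored against known answers.

## Worked example

```r
library(dvmloss)

cfg  <- dvm_scenario(days = 4, seed = 1)   # default synthetic bloom
run  <- simulate(cfg)                      # grid + ground truth
grid <- preprocess_profiles(run$grid)
iso  <- to_isopycnal(grid)
fit  <- fit_nitrate_loss(iso)
summary(fit, zrange = c(20, 36))
```

```
Nitrate loss summary
  pairs: 4910; rate estimates: 4910
  r quantiles (d-1): -0.346 / -0.009 / 0.134
  modal loss rate: 0.25 mmol N m-3 d-1; max Nloss: 9.52 mmol N m-3
  mean 20-36 m integrated loss rate: 19.6 +/- 0.2 mmol N m-2 d-1 (275 +/- 2.78 mg N m-2 d-1)
```

The fitted `nloss_fit` object reports 4,910 nitrate pairs from water-mass
reappearances; the cumulative loss reaches 9.5 mmol N m⁻³ at the
nitracline (the generator's true maximum over the same window is 10.8),
and the depth-integrated loss rate converts to mg N m⁻² d⁻¹ via the molar
mass of nitrogen. The descending chlorophyll layer is recovered at

```r
estimate_descent_speed(iso, start = 0.25 + 1 + 4/24, window_h = 10)
#> descent_track: 388 +/- 1 um s-1 (33.5 m d-1) over 1.42-1.83 d
```

within 3% of the configured 380 μm s⁻¹ swimming speed. The whole chain in
one call, with every stage written to disk:

```r
res <- run_pipeline(seed = 1, out_dir = "bloom_run")
res$summary$correlation_chl     # 0.98: nitrate loss tracks biomass gain
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/dvmloss.R`
(`Rscript dvmloss.R run-all --config cfg.yaml --seed 1 --out run/`).

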