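#' Scenario configuration for the synthetic profiler ocean
#'
#' Builds a validated configuration describing a stratified coastal water
#' column sampled by a moored profiler: a stable background density profile
#' heaved by internal waves, oscillating along-isopycnal advection carrying
#' spice (temperature-salinity) anomalies, a nitracline tied to temperature
#' through a climatological line, a chlorophyll layer performing
#' light-triggered diel vertical migration, and prescribed nitrate uptake at
#' depth. The configuration is consumed by [simulate.dvm_scenario()].
#'
#' Times are days since record start; `hour0` is the local clock hour at
#' t = 0 (default 12, i.e. records start at local noon). The solar day is
#' fixed at 06:00-18:00 local; the migrating layer starts its descent at
#' `descent_start_h` (default 18:00 local).
#'
#' @param z_max bottom of the sampled column (m), cell-centered 1-m bins.
#' @param dz vertical grid step (m).
#' @param days record length (d).
#' @param dt_min temporal grid step (minutes).
#' @param hour0 local clock hour at t = 0.
#' @param sigma_surface,sigma_deep surface and deep potential density anomaly
#'   sigma-theta (kg m^-3); must satisfy `sigma_deep > sigma_surface`.
#' @param pycnocline_depth,pycnocline_width centre and width of the tanh
#'   pycnocline (m).
#' @param sigma_gradient weak uniform background stratification
#'   (kg m^-3 per m) superposed on the pycnocline, so isopycnals exist
#'   right to the surface as in strongly heated, freshwater-capped bloom
#'   conditions; must leave `sigma_gradient * z_max` below the
#'   surface-to-deep density contrast.
#' @param t_surface,t_deep temperatures (degC) co-generated with density so
#'   the nitrate-temperature climatology is reproducible.
#' @param s_ref reference salinity (PSS-78) at the surface.
#' @param alpha,beta linear equation-of-state coefficients
#'   (kg m^-3 per degC, kg m^-3 per salinity unit).
#' @param iw_amplitude internal-wave displacement amplitude at the mode
#'   maximum (m); peak-to-trough isopycnal excursion is twice this.
#' @param iw_period_h internal-wave period (h).
#' @param iw_phase internal-wave phase (rad).
#' @param adv_period_h period of the oscillating along-isopycnal advection
#'   (h); the same water parcels reappear at the mooring each cycle.
#' @param spice_amplitude amplitude of the advected spice anomaly (kg m^-3).
#' @param residence_depth daytime residence depth of the layer centre (m).
#' @param descent_speed downward swimming speed (micrometres per second).
#' @param descent_start_h local hour at which descent begins.
#' @param layer_sigma Gaussian half-width of the chlorophyll layer (m).
#' @param dvm_floor maximum migration depth (m), nominally the nitracline.
#' @param ascent_hours duration of the dawn-side return ascent (h).
#' @param chl_background initial peak chlorophyll of the layer (mg m^-3).
#' @param uptake_max maximum volumetric uptake rate (mmol N m^-3 d^-1).
#' @param uptake_zmin,uptake_zmax active depth range of uptake (m).
#' @param half_saturation Michaelis-Menten half-saturation (mmol m^-3).
#' @param biomass_min chlorophyll presence threshold for uptake (mg m^-3).
#' @param chl_yield chlorophyll produced per nitrogen taken up
#'   (mg Chl per mmol N).
#' @param clim_slope,clim_intercept nitrate-temperature climatological line
#'   N = intercept + slope * T (mmol m^-3, valid T < `clim_cutoff`).
#' @param clim_cutoff temperature (degC) above which the line is not applied.
#' @param par_surface clear-sky noon surface PAR (umol photons m^-2 s^-1).
#' @param k_water,k_chl diffuse attenuation: clear-water part (m^-1) and
#'   chlorophyll-specific part (m^-1 per mg Chl m^-3).
#' @param n_channels number of downwelling irradiance channels emitted.
#' @param bbp_dark,bbp_per_chl optical backscatter dark offset (m^-1 sr^-1)
#'   and backscatter per unit chlorophyll.
#' @param noise_nitrate,noise_chl,noise_temperature,noise_salinity,noise_bbp
#'   i.i.d. Gaussian sensor noise standard deviations (per-sample).
#' @param seed RNG seed; a fixed seed makes the simulation byte-identical.
#'
#' @return An object of class `"dvm_scenario"` (a validated list).
#' @seealso [simulate.dvm_scenario()], [dvm_center_depth()], [apply_uptake()]
#' @examples
#' cfg <- dvm_scenario(days = 2, seed = 1)
#' cfg
#' @export
dvm_scenario <- function(z_max = 100, dz = 1, days = 14, dt_min = 15,
                         hour0 = 12,
                         sigma_surface = 24.4, sigma_deep = 25.7,
                         pycnocline_depth = 20, pycnocline_width = 8,
                         sigma_gradient = 0.008,
                         t_surface = 19, t_deep = 10, s_ref = 33.5,
                         alpha = 0.2, beta = 0.78,
                         iw_amplitude = 10, iw_period_h = 6, iw_phase = 0,
                         adv_period_h = 18, spice_amplitude = 0.02,
                         residence_depth = 4, descent_speed = 380,
                         descent_start_h = 18, layer_sigma = 3,
                         dvm_floor = 32, ascent_hours = 2,
                         chl_background = 5,
                         uptake_max = 6, uptake_zmin = 25, uptake_zmax = 35,
                         half_saturation = 0.5, biomass_min = 0.1,
                         chl_yield = 0.19,
                         clim_slope = -5.9, clim_intercept = 80.94,
                         clim_cutoff = 14,
                         par_surface = 2000, k_water = 0.12, k_chl = 0.035,
                         n_channels = 3,
                         bbp_dark = 0.001, bbp_per_chl = 0.002,
                         noise_nitrate = 0.3, noise_chl = 0.05,
                         noise_temperature = 0.005, noise_salinity = 0.005,
                         noise_bbp = 1e-5,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(z_max > 0, dz > 0, days > 0, dt_min > 0)
  if (!(sigma_deep > sigma_surface) || pycnocline_width <= 0 ||
      sigma_gradient < 0 ||
      sigma_gradient * z_max >= (sigma_deep - sigma_surface))
    stop("background density must be strictly increasing with depth")
  if (descent_speed < 0) stop("descent speed must be >= 0")
  if (dvm_floor >= z_max || residence_depth >= z_max)
    stop("DVM layer lies deeper than the sampled grid")
  if (uptake_zmin >= uptake_zmax || uptake_zmax > z_max)
    stop("uptake depth range must lie within the grid")
  if (any(c(noise_nitrate, noise_chl, noise_temperature,
            noise_salinity, noise_bbp) < 0))
    stop("noise standard deviations must be >= 0")
  if (ascent_hours <= 0 || ascent_hours >= 24)
    stop("ascent_hours must be in (0, 24)")
  structure(cfg, class = "dvm_scenario")
}

#' @export
print.dvm_scenario <- function(x, ...) {
  cat("Synthetic bloom scenario (dvm_scenario)\n")
  cat(sprintf("  grid: 0-%g m x %g m, %g d x %g min (start %02d:00 local)\n",
              x$z_max, x$dz, x$days, x$dt_min, x$hour0))
  cat(sprintf("  density: %g-%g kg m-3, pycnocline %g +/- %g m\n",
              x$sigma_surface, x$sigma_deep,
              x$pycnocline_depth, x$pycnocline_width))
  cat(sprintf("  internal waves: +/-%g m, period %g h; advection period %g h, spice +/-%g kg m-3\n",
              x$iw_amplitude, x$iw_period_h, x$adv_period_h,
              x$spice_amplitude))
  cat(sprintf("  DVM: %g um/s from %02d:00, %g -> %g m; uptake %g mmol N m-3 d-1 in %g-%g m\n",
              x$descent_speed, x$descent_start_h, x$residence_depth,
              x$dvm_floor, x$uptake_max, x$uptake_zmin, x$uptake_zmax))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

# --- background water column ------------------------------------------------

# tanh pycnocline plus a weak uniform gradient; strictly increasing in z
# for any valid config
bg_sigma <- function(z, cfg) {
  grad <- cfg$sigma_gradient %||% 0
  cfg$sigma_surface + grad * z +
    (cfg$sigma_deep - cfg$sigma_surface - grad * cfg$z_max) *
    (1 + tanh((z - cfg$pycnocline_depth) / cfg$pycnocline_width)) / 2
}

# thermocline co-located with the pycnocline; T is strictly monotone in
# density, so nitrate (linear in T) is single-valued on isopycnals
bg_temperature <- function(z, cfg) {
  frac <- (1 + tanh((z - cfg$pycnocline_depth) / cfg$pycnocline_width)) / 2
  cfg$t_surface + (cfg$t_deep - cfg$t_surface) * frac
}

# salinity closing the linear equation of state
# sigma = sigma(0) - alpha (T - T_surface) + beta (S - s_ref)
bg_salinity <- function(z, cfg) {
  cfg$s_ref + (bg_sigma(z, cfg) - bg_sigma(0, cfg) +
                 cfg$alpha * (bg_temperature(z, cfg) - cfg$t_surface)) /
    cfg$beta
}

# climatological nitrate from temperature, clipped below at zero
clim_nitrate <- function(temp, cfg) {
  pmax(0, cfg$clim_intercept + cfg$clim_slope * temp)
}

#' Depth of the migrating layer centre at a given time
#'
#' Piecewise-linear diel trajectory of the chlorophyll-layer centre: the
#' layer rests at `residence_depth` until the first descent trigger
#' (`descent_start_h` local, default 18:00), then each 24-h cycle descends at
#' `descent_speed` until it reaches `dvm_floor` (nominally the nitracline),
#' resides there, and swims back up over the final `ascent_hours` of the
#' cycle so it is back at the residence depth by the next trigger.
#'
#' @param t time in days since record start (vectorised).
#' @param config a [dvm_scenario()] object.
#' @return layer-centre depth (m, positive downward).
#' @examples
#' cfg <- dvm_scenario()
#' dvm_center_depth(0, cfg)              # local noon, pre-descent: 4 m
#' dvm_center_depth(0.25 + 10 / 24, cfg) # 10 h into the first descent
#' @export
dvm_center_depth <- function(t, config) {
  cfg <- config
  w_mh <- cfg$descent_speed * 3.6e-3        # um/s -> m/h
  t_first <- ((cfg$descent_start_h - cfg$hour0) %% 24) / 24
  h_up <- 24 - cfg$ascent_hours
  floor_z <- max(cfg$dvm_floor, cfg$residence_depth)
  depth <- rep(cfg$residence_depth, length(t))
  act <- t >= t_first
  if (any(act)) {
    h <- ((t[act] - t_first) * 24) %% 24    # hours since last descent start
    zd <- pmin(cfg$residence_depth + w_mh * h, floor_z)
    z_up <- min(cfg$residence_depth + w_mh * h_up, floor_z)
    asc <- h >= h_up
    zd[asc] <- z_up + (cfg$residence_depth - z_up) *
      (h[asc] - h_up) / cfg$ascent_hours
    depth[act] <- zd
  }
  depth
}

# Michaelis-Menten uptake kernel shared by apply_uptake() and the simulator:
# active depth window, biomass presence, nitrate saturation
uptake_rate_kernel <- function(nitrate, biomass, z, cfg) {
  active <- as.numeric(z >= cfg$uptake_zmin & z <= cfg$uptake_zmax)
  present <- as.numeric(biomass > cfg$biomass_min)
  cfg$uptake_max * active * present * nitrate / (nitrate + cfg$half_saturation)
}

#' Apply prescribed nitrate uptake to a field and record the ground truth
#'
#' Steps a nitrate field forward in time, removing nitrate wherever the
#' biomass field overlaps the configured active depth range. Uptake follows
#' Michaelis-Menten saturation in nitrate, is floored so nitrate never goes
#' negative, and the realised volumetric loss rate and its cumulative time
#' integral are recorded exactly.
#'
#' `nitrate` is interpreted as the field the water column would show with no
#' uptake (advection and heaving already included); the returned field is
#' that input minus the accumulated uptake, floored at zero.
#'
#' @param nitrate depth x time matrix of nitrate (mmol m^-3) without uptake.
#' @param biomass depth x time matrix of chlorophyll (mg m^-3).
#' @param config a [dvm_scenario()] object (uptake parameters are read from
#'   it).
#' @param z depth axis (m) of the rows.
#' @param time time axis (d) of the columns; step must be <= 15 min.
#' @return list with `nitrate` (modified field), `rho_true` (realised loss
#'   rate, mmol N m^-3 d^-1) and `nloss_true` (its cumulative trapezoidal
#'   time integral, mmol N m^-3).
#' @examples
#' cfg <- dvm_scenario(uptake_zmin = 0, uptake_zmax = 100,
#'                     half_saturation = 0.1)
#' tt <- seq(0, 1, by = 15 / 1440)
#' n <- matrix(20, 3, length(tt))
#' b <- matrix(5, 3, length(tt))
#' out <- apply_uptake(n, b, cfg, z = c(10, 20, 30), time = tt)
#' out$nitrate[1, ncol(n)]   # ~ 20 - 6 after one day
#' @export
apply_uptake <- function(nitrate, biomass, config, z, time) {
  if (any(nitrate < 0)) stop("input nitrate field has negative values")
  stopifnot(all(dim(nitrate) == dim(biomass)),
            nrow(nitrate) == length(z), ncol(nitrate) == length(time))
  if (length(time) > 1 && max(diff(time)) > 15 / 1440 + 1e-9)
    stop("time step must be <= 15 min")
  nt <- length(time)
  rho <- matrix(0, nrow(nitrate), nt)
  ucum <- numeric(nrow(nitrate))
  nout <- nitrate
  if (nt > 1) {
    for (k in seq_len(nt - 1L)) {
      dt <- time[k + 1L] - time[k]
      r <- uptake_rate_kernel(nout[, k], biomass[, k], z, config)
      cand <- pmax(0, nitrate[, k + 1L] - ucum)   # no-uptake-this-step value
      nxt <- pmax(0, cand - r * dt)
      rho[, k] <- (cand - nxt) / dt               # realised rate incl. floor
      ucum <- ucum + rho[, k] * dt
      nout[, k + 1L] <- nxt
    }
  }
  nloss <- t(apply(rho, 1L, function(y) cumtrapz(time, y)))
  list(nitrate = nout, rho_true = rho, nloss_true = nloss)
}
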