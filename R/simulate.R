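#' Simulate a profiler record of a migrating dinoflagellate bloom
#'
#' Generates a synthetic depth-time record of temperature, salinity,
#' density, nitrate, chlorophyll fluorescence, optical backscatter and
#' downwelling irradiance, as a moored profiler would observe it, together
#' with the ground truth needed to score every analysis stage.
#'
#' The water column is built in an isopycnal "label" coordinate (the rest
#' depth of each isopycnal). On that coordinate: nitrate is the
#' climatological function of temperature minus the accumulated prescribed
#' uptake; along-isopycnal advection carries a density-compensated
#' temperature/salinity (spice) anomaly oscillating with period
#' `adv_period_h`, so the same parcels reappear at the mooring; the
#' chlorophyll layer is a Gaussian centred on the diel migration trajectory
#' [dvm_center_depth()], its integral growing by `chl_yield` times the
#' accumulated uptake. Internal waves then heave the whole column: every
#' observed field at depth z and time t is the label field evaluated at
#' z - eta(z, t), which is exactly the assumption the isopycnal transform
#' inverts. Gaussian sensor noise is added last; ground truth is recorded
#' before noise.
#'
#' @param object a [dvm_scenario()] configuration.
#' @param nsim number of records (only 1 supported).
#' @param seed optional override of the configuration seed.
#' @param ... unused.
#' @return list with elements `grid` (a [profile_grid()] with variables
#'   `temperature`, `salinity`, `sigma_theta`, `nitrate`, `chl`, `bbp`,
#'   `par` and irradiance channels `ed1..edK`) and `truth` (class
#'   `"ground_truth"`: isopycnal displacement `eta`, layer trajectory
#'   `z_center`, parcel phase `xi`, spice anomaly series, and on the label
#'   grid the noise-free nitrate, chlorophyll, realised uptake `rho_true`
#'   and cumulative `nloss_true`).
#' @examples
#' run <- simulate(dvm_scenario(days = 2, seed = 7))
#' run$grid
#' max(run$truth$nloss_true)
#' @export
simulate.dvm_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  z <- seq(cfg$dz / 2, cfg$z_max - cfg$dz / 2, by = cfg$dz)
  dt <- cfg$dt_min / 1440
  time <- seq(0, cfg$days, by = dt)
  nz <- length(z); nt <- length(time)

  ## --- label-coordinate (isopycnal rest depth) fields ---
  t_bg <- bg_temperature(z, cfg)
  s_bg <- bg_salinity(z, cfg)
  xi <- if (cfg$adv_period_h > 0) sin(2 * pi * time * 24 / cfg$adv_period_h)
        else rep(0, nt)
  theta_amp <- if (cfg$alpha > 0) cfg$spice_amplitude / (2 * cfg$alpha) else 0
  t_anom <- theta_amp * xi                      # advected, uniform in z
  s_anom <- (cfg$alpha / cfg$beta) * t_anom     # density-compensated

  # nitrate each parcel carries (before uptake): climatology of its own T
  n_parcel <- vapply(seq_len(nt), function(k)
    clim_nitrate(t_bg + t_anom[k], cfg), numeric(nz))

  ## --- DVM layer and uptake (coupled: chlorophyll grows with uptake) ---
  z_c <- dvm_center_depth(time, cfg)
  gauss_norm <- cfg$layer_sigma * sqrt(2 * pi)
  chl_lab <- matrix(0, nz, nt)
  n_lab <- n_parcel
  rho_true <- matrix(0, nz, nt)
  ucum <- numeric(nz)
  for (k in seq_len(nt)) {
    peak <- cfg$chl_background +
      cfg$chl_yield * sum(ucum) * cfg$dz / gauss_norm
    chl_lab[, k] <- peak * exp(-(z - z_c[k])^2 / (2 * cfg$layer_sigma^2))
    if (k < nt) {
      r <- uptake_rate_kernel(n_lab[, k], chl_lab[, k], z, cfg)
      cand <- pmax(0, n_parcel[, k + 1L] - ucum)
      nxt <- pmax(0, cand - r * dt)
      rho_true[, k] <- (cand - nxt) / dt
      ucum <- ucum + rho_true[, k] * dt
      n_lab[, k + 1L] <- nxt
    }
  }
  nloss_true <- t(apply(rho_true, 1L, function(y) cumtrapz(time, y)))
  bbp_lab <- cfg$bbp_dark + cfg$bbp_per_chl * chl_lab

  ## --- internal-wave heaving: map label fields to observation depths ---
  mode_z <- sin(pi * z / cfg$z_max)
  phase_t <- if (cfg$iw_period_h > 0)
    sin(2 * pi * time * 24 / cfg$iw_period_h + cfg$iw_phase) else rep(0, nt)
  eta <- cfg$iw_amplitude * (mode_z %o% phase_t)

  sig_e <- temp_e <- sal_e <- nitr_e <- chl_e <- bbp_e <- matrix(0, nz, nt)
  for (k in seq_len(nt)) {
    zlab <- clamp(z - eta[, k], z[1], z[nz])
    sig_e[, k] <- bg_sigma(zlab, cfg)
    temp_e[, k] <- bg_temperature(zlab, cfg) + t_anom[k]
    sal_e[, k] <- bg_salinity(zlab, cfg) + s_anom[k]
    nitr_e[, k] <- stats::approx(z, n_lab[, k], xout = zlab, rule = 2)$y
    chl_e[, k] <- stats::approx(z, chl_lab[, k], xout = zlab, rule = 2)$y
  }
  bbp_e <- cfg$bbp_dark + cfg$bbp_per_chl * chl_e

  ## --- light: diurnal surface PAR attenuated by water + chlorophyll ---
  h <- local_hour(time, cfg$hour0)
  par0 <- cfg$par_surface * pmax(0, sin(pi * (h - 6) / 12))
  kext <- cfg$k_water + cfg$k_chl * chl_e
  # optical depth to each cell centre
  od <- apply(kext * cfg$dz, 2L, cumsum) - kext * cfg$dz / 2
  par_e <- sweep(exp(-od), 2L, par0, `*`)

  truth <- structure(list(
    z = z, time = time, hour0 = cfg$hour0,
    eta = eta, z_center = z_c, xi = xi,
    spice_anomaly = cfg$spice_amplitude * xi,
    nitrate_true = n_lab, chl_true = chl_lab,
    rho_true = rho_true, nloss_true = nloss_true,
    uptake_cum = ucum, config = cfg), class = "ground_truth")

  ## --- sensor noise (ground truth above is noise-free) ---
  noisy <- function(m, sd) if (sd > 0) m + stats::rnorm(length(m), 0, sd) else m
  vars <- list(
    temperature = noisy(temp_e, cfg$noise_temperature),
    salinity    = noisy(sal_e, cfg$noise_salinity),
    sigma_theta = sig_e,
    nitrate     = noisy(nitr_e, cfg$noise_nitrate),
    chl         = noisy(chl_e, cfg$noise_chl),
    bbp         = noisy(bbp_e, cfg$noise_bbp),
    par         = par_e)
  for (j in seq_len(cfg$n_channels)) vars[[paste0("ed", j)]] <- par_e

  list(grid = profile_grid(z, time, vars, hour0 = cfg$hour0),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth for synthetic scenario\n")
  cat(sprintf("  max cumulative loss: %.3f mmol N m-3; column uptake: %.2f mmol N m-2\n",
              max(x$nloss_true), sum(x$uptake_cum) * diff(x$z[1:2])))
  cat(sprintf("  layer centre range: %.1f-%.1f m; IW displacement range: %.1f to %.1f m\n",
              min(x$z_center), max(x$z_center), min(x$eta), max(x$eta)))
  invisible(x)
}
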