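# Shared fixture builders; everything is generated in code at test time.

scenario_with <- function(base, ...) {
  do.call(dvm_scenario, utils::modifyList(base, list(...)))
}

# quiet short scenario: no forcing at all
quiet_scenario <- function(days = 1, ...) {
  scenario_with(list(days = days, iw_amplitude = 0, adv_period_h = 0,
                     spice_amplitude = 0, uptake_max = 0,
                     noise_nitrate = 0, noise_chl = 0,
                     noise_temperature = 0, noise_salinity = 0,
                     noise_bbp = 0, seed = 1), ...)
}

# physics on (internal waves + advection), biology and noise off
physics_scenario <- function(days = 2, ...) {
  scenario_with(list(days = days, uptake_max = 0,
                     noise_nitrate = 0, noise_chl = 0,
                     noise_temperature = 0, noise_salinity = 0,
                     noise_bbp = 0, seed = 1), ...)
}

# stationary deep layer with continuous saturating uptake in 60-70 m,
# where the nitrate reservoir (~20 mmol m-3) exceeds the imposed loss
deep_uptake_scenario <- function(days = 3, ...) {
  scenario_with(list(days = days, descent_speed = 0,
                     residence_depth = 65, layer_sigma = 4,
                     uptake_zmin = 60, uptake_zmax = 70,
                     half_saturation = 0.01, seed = 1), ...)
}

# forward-Euler oracle for Michaelis-Menten uptake of a single cell
euler_uptake_oracle <- function(n0, vmax, ks, days, dt_days = 1 / 1440) {
  n <- n0
  for (i in seq_len(round(days / dt_days)))
    n <- max(0, n - vmax * n / (n + ks) * dt_days)
  n
}

# minimal hand-built nloss_fit-like object for depth integration tests
fake_fit <- function(mean_depth, time, nloss, nloss_se = NULL,
                     rho = NULL, rho_se = NULL, native_dz = 0) {
  z <- matrix(0, length(mean_depth), length(time))
  structure(list(sigma = seq_along(mean_depth), time = time,
                 mean_depth = mean_depth,
                 nloss = nloss, nloss_se = nloss_se %||% (nloss * 0),
                 rho = rho %||% z, rho_se = rho_se %||% z,
                 native_dz = native_dz),
            class = "nloss_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
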