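test_that("invalid scenario configurations are rejected", {
  expect_error(dvm_scenario(sigma_deep = 24), "increasing")
  expect_error(dvm_scenario(descent_speed = -1), ">= 0")
  expect_error(dvm_scenario(dvm_floor = 200), "deeper than")
  expect_error(dvm_scenario(uptake_zmin = 50, uptake_zmax = 40), "uptake")
})

test_that("without forcing, density and nitrate are constant in time", {
  run <- simulate(quiet_scenario())
  for (v in c("sigma_theta", "nitrate")) {
    m <- run$grid$vars[[v]]
    expect_equal(max(apply(m, 1, function(x) diff(range(x)))), 0)
  }
})

test_that("fixed seed reproduces the simulation byte-identically", {
  a <- simulate(dvm_scenario(days = 1, seed = 42))
  b <- simulate(dvm_scenario(days = 1, seed = 42))
  expect_identical(a$grid, b$grid)
  expect_identical(a$truth$nloss_true, b$truth$nloss_true)
})

test_that("layer centre follows the diel trajectory", {
  cfg <- dvm_scenario()
  # record starts at local noon, before the first descent
  expect_equal(dvm_center_depth(0, cfg), cfg$residence_depth)
  # linear kinematics: 380 um/s for 10 h from 4 m
  t10 <- 0.25 + 10 / 24                 # 18:00 trigger + 10 h
  expect_equal(dvm_center_depth(t10, cfg), 4 + 0.00038 * 36000,
               tolerance = 1e-10)
  # zero speed: depth constant at residence
  cfg0 <- dvm_scenario(descent_speed = 0)
  tt <- seq(0, 3, by = 0.01)
  expect_true(all(dvm_center_depth(tt, cfg0) == cfg0$residence_depth))
  # speed never exceeds the configured floor
  expect_true(all(dvm_center_depth(tt, cfg) <= cfg$dvm_floor))
})

test_that("prescribed uptake saturates, floors at zero and logs truth", {
  cfg <- dvm_scenario(uptake_zmin = 0, uptake_zmax = 100,
                      half_saturation = 0.1)
  tt <- seq(0, 1, by = 15 / 1440)
  z <- c(10, 20, 30)
  b <- matrix(5, 3, length(tt))
  # no consumers: nitrate unchanged, no loss
  out0 <- apply_uptake(matrix(20, 3, length(tt)), b * 0, cfg, z, tt)
  expect_equal(out0$nitrate, matrix(20, 3, length(tt)))
  expect_true(all(out0$nloss_true == 0))
  # nitrate zero stays zero
  outz <- apply_uptake(matrix(0, 3, length(tt)), b, cfg, z, tt)
  expect_true(all(outz$nitrate == 0))
  expect_true(all(outz$nitrate >= 0))
  # forward-Euler oracle at 1-min steps: N0 = 20 >> Ks, 1 day at 6/d
  oracle <- euler_uptake_oracle(20, 6, 0.1, 1)
  out <- apply_uptake(matrix(20, 3, length(tt)), b, cfg, z, tt)
  expect_equal(out$nitrate[1, length(tt)], 14, tolerance = 0.1)
  expect_equal(out$nitrate[1, length(tt)], oracle, tolerance = 0.05)
  # negative input refused
  expect_error(apply_uptake(matrix(-0.1, 3, length(tt)), b, cfg, z, tt),
               "negative")
})

test_that("saturating uptake in a thick layer integrates to rate x time x thickness", {
  run <- simulate(deep_uptake_scenario(days = 2.5))
  tr <- run$truth
  expect_equal(max(tr$nloss_true), 6 * 2.5, tolerance = 0.02 * 15)
  expect_equal(max(colSums(tr$nloss_true)), 6 * 2.5 * 10,
               tolerance = 0.05 * 150)
})

test_that("ground truth is internally consistent", {
  run <- simulate(dvm_scenario(days = 2, seed = 3))
  tr <- run$truth
  # cumulative loss is the trapezoidal integral of the rate field
  nl <- t(apply(tr$rho_true, 1, function(y) {
    c(0, cumsum((y[-1] + y[-length(y)]) * diff(tr$time) / 2))
  }))
  expect_equal(tr$nloss_true, nl, tolerance = 1e-12)
  # non-decreasing in time
  expect_true(all(diff(t(tr$nloss_true)) >= -1e-12))
  # no uptake outside the active depth range
  outside <- tr$z < run$truth$config$uptake_zmin |
    tr$z > run$truth$config$uptake_zmax
  expect_true(all(tr$rho_true[outside, ] == 0))
})

test_that("total nitrate removed matches the integrated true rate field", {
  run <- simulate(deep_uptake_scenario(days = 2))
  tr <- run$truth
  dz <- diff(tr$z[1:2])
  removed <- sum(tr$uptake_cum) * dz
  integ <- sum(vapply(seq_len(nrow(tr$rho_true)), function(i) {
    y <- tr$rho_true[i, ]
    sum((y[-1] + y[-length(y)]) * diff(tr$time) / 2)
  }, numeric(1))) * dz
  expect_equal(integ, removed, tolerance = 0.005 * removed)
})

test_that("isopycnal displacement peak-to-trough matches the configuration", {
  run <- simulate(physics_scenario())
  p2t <- max(run$truth$eta) - min(run$truth$eta)
  expect_equal(p2t, 2 * 10, tolerance = 0.05 * 20)
})

test_that("with zero noise and uptake, nitrate is a function of water-mass identity", {
  run <- simulate(physics_scenario(days = 2))
  iso <- to_isopycnal(run$grid)
  sp <- compute_spice(iso$vars$temperature, iso$vars$salinity)
  # within each (isopycnal, fine spice bin) class nitrate is constant to
  # interpolation accuracy
  for (i in c(20, 35, 50)) {
    lab <- round(sp[i, ] / 1e-4)
    ok <- iso$valid[i, ] & is.finite(lab)
    spread <- tapply(iso$vars$nitrate[i, ok], lab[ok],
                     function(x) diff(range(x)))
    expect_lt(stats::median(spread, na.rm = TRUE), 1e-3)
  }
})
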