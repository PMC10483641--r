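test_that("two-point and multi-point rate fits recover exact exponentials", {
  # no change -> zero rate
  expect_equal(fit_rate(c(7, 7), c(0, 1))$r, 0)
  # closed-form log ratio
  f <- fit_rate(c(10, 5), c(0, 1))
  expect_equal(f$r, log(0.5), tolerance = 1e-15)
  expect_equal(f$r, -0.6931, tolerance = 1e-4)
  # delta-method SE for a pair
  f2 <- fit_rate(c(10, 5), c(0, 2), se = c(0.3, 0.3))
  expect_equal(f2$se, sqrt((0.3 / 10)^2 + (0.3 / 5)^2) / 2,
               tolerance = 1e-12)
  # exact exponential through three visits
  tt <- 0:2
  f3 <- fit_rate(8 * exp(-0.5 * tt), tt)
  expect_equal(f3$r, -0.5, tolerance = 1e-12)
  # undetectable values are refused, not treated as zero rate
  expect_error(fit_rate(c(0.4, 5), c(0, 1)), "refused")
})

test_that("rate gridding averages overlapping estimates with inverse-variance weights", {
  time <- seq(0, 1, by = 0.25)
  # two estimates covering the same window, equal SE -> plain mean
  wm <- dvmloss:::rate_weight_matrix(t1 = c(0, 0), t2 = c(1, 1),
                                     se = c(0.1, 0.1), time, gap_limit = 1)
  r <- as.numeric(wm$A %*% c(-0.2, -0.4))
  expect_equal(r, rep(-0.3, 5))
  # single estimate: field equals the estimate where covered
  wm1 <- dvmloss:::rate_weight_matrix(0.2, 0.6, 0.1, time, gap_limit = 1)
  expect_equal(as.numeric(wm1$A %*% -0.7)[2:3], rep(-0.7, 2))
  expect_equal(wm1$status[1], 2L)       # before coverage: no information
  # unequal SEs weight 1/se^2
  wm2 <- dvmloss:::rate_weight_matrix(c(0, 0), c(1, 1), c(0.1, 0.2),
                                      time, gap_limit = 1)
  r2 <- as.numeric(wm2$A %*% c(0, 1))[1]
  expect_equal(r2, (1 / 0.04) / (1 / 0.01 + 1 / 0.04), tolerance = 1e-12)
  # gaps wider than the limit stay flagged
  wm3 <- dvmloss:::rate_weight_matrix(c(0, 0.9), c(0.1, 1), c(0.1, 0.1),
                                      time, gap_limit = 0.5)
  expect_equal(wm3$status[3], 2L)
})

test_that("loss iteration reproduces closed forms and conserves by construction", {
  run <- simulate(deep_uptake_scenario(days = 2))
  fit <- fit_nitrate_loss(to_isopycnal(preprocess_profiles(run$grid)))
  # consistency: cumulative sum of rho * dt equals nloss exactly
  i <- which.max(suppressWarnings(apply(fit$nloss, 1, max, na.rm = TRUE)))
  ok <- which(!is.na(fit$rho[i, ]) & !is.na(fit$nloss[i, ]))
  recon <- cumsum(ifelse(is.na(fit$rho[i, ]), 0, fit$rho[i, ])) * fit$dt
  k <- max(ok) - 1
  expect_equal(fit$nloss[i, k + 1],
               sum(fit$rho[i, seq_len(k)], na.rm = TRUE) * fit$dt,
               tolerance = 1e-10)
  # r = 0 -> static nitrate, zero loss, exactly
  time <- seq(0, 2, by = 15 / 1440)
  temp <- 12 + 0.05 * sin(2 * pi * time * 24 / 6)
  iso0 <- structure(list(
    sigma = 25, time = time, depth = matrix(30, 1, length(time)),
    vars = list(nitrate = matrix(8, 1, length(time)),
                temperature = matrix(temp, 1, length(time)),
                salinity = matrix(33.5, 1, length(time))),
    valid = matrix(TRUE, 1, length(time)), native_dz = 1),
    class = "iso_grid")
  fq <- fit_nitrate_loss(iso0, nitrate_se = 1e-6)
  expect_gt(nrow(fq$rates), 0)
  expect_equal(max(abs(fq$rates$r)), 0)
  expect_equal(max(fq$nloss, na.rm = TRUE), 0)
  expect_equal(stats::sd(fq$nhat[1, ]), 0)
})

test_that("constant-rate decay matches its analytic loss", {
  # r = -0.1 per day from N0 = 10: loss after 1 d is 10(1 - e^-0.1).
  # An oscillating spice signature creates the water-mass reappearances
  # that carry the rate information.
  time <- seq(0, 1, by = 15 / 1440)
  temp <- 12 + 0.05 * sin(2 * pi * time * 24 / 6)
  iso <- structure(list(
    sigma = 25, time = time, depth = matrix(30, 1, length(time)),
    vars = list(nitrate = matrix(10 * exp(-0.1 * time), 1, length(time)),
                temperature = matrix(temp, 1, length(time)),
                salinity = matrix(33.5, 1, length(time))),
    valid = matrix(TRUE, 1, length(time)), native_dz = 1),
    class = "iso_grid")
  fit <- fit_nitrate_loss(iso, nitrate_se = 1e-9, max_dt = 2)
  expect_gt(nrow(fit$pairs), 3)
  expect_equal(stats::median(fit$rates$r), -0.1, tolerance = 1e-3)
  nt <- length(time)
  expect_equal(fit$nloss[1, nt], 10 * (1 - exp(-0.1)), tolerance = 0.02)
  expect_equal(fit$nloss[1, nt], 0.9516, tolerance = 0.02)
})

test_that("imposed uptake is recovered within tolerance against ground truth", {
  run <- simulate(deep_uptake_scenario(days = 3))
  tr <- run$truth
  fit <- fit_nitrate_loss(to_isopycnal(preprocess_profiles(run$grid)))
  # cumulative loss vs truth on the estimator's support (density bins,
  # compared at each bin's mean depth): relative RMSE < 25%
  k_end <- length(fit$time)
  true_end <- tr$nloss_true[, ncol(tr$nloss_true)]
  md <- fit$mean_depth
  sel <- which(is.finite(md) & md >= 55 & md <= 75 &
                 is.finite(fit$nloss[, k_end]))
  est <- fit$nloss[sel, k_end]
  tru <- stats::approx(tr$z, true_end, xout = md[sel], rule = 2)$y
  act <- tru > 1
  rel_rmse <- sqrt(mean((est[act] - tru[act])^2)) / mean(tru[act])
  expect_lt(rel_rmse, 0.25)
})

test_that("halving the nitrate noise halves the median rate SE", {
  med_se <- vapply(c(0.3, 0.15), function(ns) {
    run <- simulate(dvm_scenario(days = 2, seed = 8, uptake_max = 0,
                                 noise_nitrate = ns))
    iso <- to_isopycnal(preprocess_profiles(run$grid))
    fit <- fit_nitrate_loss(iso, nitrate_se = ns)
    stats::median(fit$rates$se)
  }, numeric(1))
  expect_equal(med_se[2] / med_se[1], 0.5, tolerance = 0.1)
})

test_that("depth integration applies the trapezoid rule with flags", {
  tt <- 0:2
  md <- 0:33
  # constant 1 mmol m-3 over 0-33 m -> 33 mmol m-2
  f <- fake_fit(md, tt, matrix(1, 34, 3))
  expect_equal(depth_integrate(f, 0, 33)$value, rep(33, 3))
  # rectangle: rho = 6 over a 10-m sub-layer
  rho <- matrix(0, 34, 3); rho[md >= 10 & md <= 20, ] <- 6
  f2 <- fake_fit(md, tt, matrix(0, 34, 3), rho = rho)
  expect_equal(depth_integrate(f2, 0, 33, what = "rho")$value[1], 60,
               tolerance = 6)            # trapezoid edge cells
  # triangular profile: peak 12 at 25 m, zero at 15/35 m -> 120 mmol m-2
  md3 <- 0:40
  tri <- pmax(0, 12 * (1 - abs(md3 - 25) / 10))
  oracle <- sum((tri[-1] + tri[-41]) / 2)      # trapezoid at 1-m nodes
  f3 <- fake_fit(md3, tt, matrix(tri, 41, 3))
  expect_equal(depth_integrate(f3, 0, 40)$value[1], oracle)
  expect_equal(oracle, 120, tolerance = 1)
  # more than half the range missing -> flagged
  m4 <- matrix(1, 34, 3); m4[1:20, 2] <- NA
  f4 <- fake_fit(md, tt, m4)
  expect_true(depth_integrate(f4, 0, 33)$flag[2])
})

test_that("flux and speed unit conversions match printed precision", {
  expect_equal(convert_flux_units(31)$value, 434)
  expect_equal(convert_flux_units(31, 4)$se, 56.0)
  expect_equal(convert_flux_units(0)$value, 0)
  expect_equal(convert_speed_units(380), 1.4)
})

test_that("the fitted model object supports the standard methods", {
  run <- simulate(deep_uptake_scenario(days = 2))
  fit <- fit_nitrate_loss(to_isopycnal(preprocess_profiles(run$grid)))
  expect_s3_class(fit, "nloss_fit")
  expect_output(print(fit), "nitrate loss")
  s <- summary(fit, zrange = c(55, 75))
  expect_output(print(s), "modal loss rate")
  expect_true(is.finite(s$mean_integrated_rate))
  cf <- coef(fit)
  expect_equal(length(cf), length(fit$sigma))
  p <- predict(fit, newtime = c(0.5, 1))
  expect_equal(dim(p), c(length(fit$sigma), 2L))
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pdf_file))
  unlink(pdf_file)
})
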