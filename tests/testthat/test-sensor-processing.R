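test_that("nitrate QC despikes against a brute-force median/MAD oracle", {
  # clean constant series passes through untouched
  q <- qc_nitrate(rep(10, 5), window = 3)
  expect_equal(q$value, rep(10, 5))
  expect_true(all(q$flag == 0))
  # single spike replaced by the local median
  x <- c(10, 10, 60, 10, 10)
  rm_ <- stats::runmed(x, 3, endrule = "median")
  resid <- x - rm_
  oracle <- x
  oracle[abs(resid) > 5 * stats::mad(resid)] <-
    rm_[abs(resid) > 5 * stats::mad(resid)]
  q <- qc_nitrate(x, window = 3)
  expect_equal(q$value, oracle)
  expect_equal(q$flag, c(0L, 0L, 1L, 0L, 0L))
  # everything below the detection limit is flagged and zeroed
  q <- qc_nitrate(rep(-0.1, 6), detection_limit = 0.5)
  expect_true(all(q$flag == 2L))
  expect_true(all(q$value == 0))
  expect_error(qc_nitrate(1:5, window = 4), "odd")
})

test_that("nitrate QC is idempotent", {
  set.seed(7)
  x <- 10 + rnorm(400, 0, 0.3)
  x[c(40, 200, 390)] <- c(60, -30, 25)
  once <- qc_nitrate(x)
  twice <- qc_nitrate(once$value)
  expect_equal(twice$value, once$value)
  expect_true(all(twice$flag[once$flag == 2L] == 2L))
})

test_that("burst samples average into depth cells", {
  z <- c(0.5, 1.5, 2.5)
  out <- average_bursts(c(0.4, 0.6, 1.4, 1.6), c(1, 3, 10, 20), z)
  expect_equal(out, c(2, 15, NA))
})

test_that("quenching correction scales with backscatter and spares the night", {
  nz <- 20; z <- seq(0.5, 19.5)
  tt <- c(0, 0.5)                       # noon (day) and midnight
  par <- matrix(rep(2000 * exp(-0.3 * z), 2), nz, 2)
  par[, 2] <- 0
  chl_true <- rep(4, nz)
  bbp <- matrix(0.001 + 0.002 * chl_true, nz, 2)
  chl <- matrix(chl_true, nz, 2)
  quench <- par[, 1] > 100              # daytime quenched region
  chl[quench, 1] <- chl_true[quench] / 2
  res <- correct_npq(chl, par, bbp, tt, hour0 = 12)
  # ratio-scaling oracle: uniform bbp, deep chl 4 -> corrected uniform 4
  expect_equal(res$chl[, 1], rep(4, nz), tolerance = 1e-10)
  # night profile untouched exactly
  expect_identical(res$chl[, 2], chl[, 2])
  # dark scenario: PAR never exceeds threshold, nothing modified
  res0 <- correct_npq(chl, par * 0, bbp, tt, hour0 = 12)
  expect_identical(res0$chl, chl)
  # correction never reduces daytime chlorophyll
  expect_true(all(res$chl[, 1] >= chl[, 1]))
  # unusable backscatter: flagged, unchanged
  resb <- correct_npq(chl, par, bbp * 0, tt, hour0 = 12)
  expect_identical(resb$chl, chl)
  expect_true(any(resb$flag[, 1] == 1L))
})

test_that("quenching correction conserves nighttime integrated chlorophyll", {
  run <- simulate(dvm_scenario(days = 1, seed = 5))
  g <- run$grid
  res <- correct_npq(g$vars$chl, g$vars$par, g$vars$bbp, g$time, g$hour0)
  night <- !((g$hour0 + g$time * 24) %% 24 >= 6 &
               (g$hour0 + g$time * 24) %% 24 < 18)
  expect_identical(res$chl[, night], g$vars$chl[, night])
})

test_that("PAR is a normalised weighted channel sum", {
  expect_equal(compute_par(list(matrix(5)))[1, 1], 5)
  expect_equal(compute_par(list(matrix(2), matrix(2)))[1, 1], 2)
  expect_equal(compute_par(list(matrix(1), matrix(3)),
                           weights = c(0.25, 0.75))[1, 1], 2.5)
  # missing channels: renormalised over those present, NA when none
  m1 <- matrix(c(1, NA)); m2 <- matrix(c(NA, NA))
  p <- compute_par(list(m1, m2))
  expect_equal(p[1, 1], 1)
  expect_true(is.na(p[2, 1]))
})

test_that("euphotic depth matches the 1% light level", {
  z <- 0:100
  r <- euphotic_depth(100 * exp(-0.3 * z), z)
  expect_equal(r$depth, log(100) / 0.3, tolerance = 0.01)
  expect_equal(r$flag, 0L)
  # root-finding oracle for a different attenuation
  k <- 0.46
  oracle <- stats::uniroot(function(zz) exp(-k * zz) - 0.01, c(0, 100),
                           tol = 1e-10)$root
  r2 <- euphotic_depth(50 * exp(-k * z), z)
  expect_equal(r2$depth, oracle, tolerance = 0.01)
  expect_equal(r2$depth, 10.01, tolerance = 0.01)
  # constant profile never crosses: unresolved at the grid bottom
  rc <- euphotic_depth(rep(10, 101), z)
  expect_equal(rc$depth, 100)
  expect_equal(rc$flag, 1L)
  # invariant to rescaling the light field
  r3 <- euphotic_depth(7.3 * 100 * exp(-0.3 * z), z)
  expect_equal(r3$depth, r$depth)
})

test_that("turbidity is affine-scaled, clipped backscatter", {
  expect_equal(estimate_turbidity(0.004, gain = 200, dark = 0.001)$turbidity,
               0.6)
  expect_equal(estimate_turbidity(0.5, gain = 1, dark = 0)$turbidity, 0.5)
  low <- estimate_turbidity(0.0005, gain = 200, dark = 0.001)
  expect_equal(low$turbidity, 0)
  expect_equal(low$flag, 1L)
})

test_that("preprocessing marks all-flagged nitrate profiles unusable", {
  run <- simulate(dvm_scenario(days = 0.5, seed = 9))
  g <- run$grid
  g$vars$nitrate[, 3] <- -1             # whole profile below detection
  clean <- preprocess_profiles(g)
  usable <- attr(clean, "profile_usable")
  expect_false(usable[3])
  expect_true(usable[4])
  expect_true(all(c("par", "turbidity") %in% names(clean$vars)))
  expect_true(all(clean$vars$nitrate[!clean$flags$nitrate] >= 0))
})
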