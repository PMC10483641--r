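#' Quality-control a nitrate series
#'
#' Despikes with a running median: points whose residual from the running
#' median exceeds `mad_factor` times the MAD of the residuals are replaced
#' by the running median, iterating until no point is flagged (which makes
#' the operation exactly idempotent). Values below the optical detection
#' limit are flagged `below_detection` and set to 0 for display; such
#' values must never enter log-space rate fits.
#'
#' @param x numeric nitrate series (mmol m^-3), e.g. one profile.
#' @param window odd running-median window length (>= 3).
#' @param detection_limit sensor detection limit (mmol m^-3).
#' @param mad_factor spike threshold in MADs.
#' @return list with `value` (cleaned series) and `flag` (integer: 0 good,
#'   1 despiked, 2 below detection).
#' @examples
#' qc_nitrate(c(10, 10, 60, 10, 10), window = 3)$value
#' @export
qc_nitrate <- function(x, window = 5, detection_limit = 0.5,
                       mad_factor = 5) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  flag <- integer(length(x))
  v <- x
  ok <- is.finite(v)
  if (sum(ok) >= window) {
    for (it in 1:20) {
      rm_ <- stats::runmed(v[ok], window, endrule = "median")
      resid <- v[ok] - rm_
      s <- stats::mad(resid)
      spike <- abs(resid) > mad_factor * s
      if (!any(spike)) break
      vv <- v[ok]; vv[spike] <- rm_[spike]; v[ok] <- vv
      flag[ok][spike] <- 1L
    }
  }
  below <- is.finite(v) & v < detection_limit
  flag[below] <- 2L
  v[below] <- 0
  list(value = v, flag = flag)
}

#' Average burst samples into depth cells
#'
#' Nitrate sensors on profilers typically burst-sample (e.g. a 20 min per
#' hour duty cycle at 1 Hz); this collapses raw samples to per-cell means
#' on the nominal 1-m grid.
#'
#' @param depth sample depths (m).
#' @param value sample values.
#' @param z target cell centres (m).
#' @return per-cell mean (NA where a cell received no samples).
#' @export
average_bursts <- function(depth, value, z) {
  dz <- if (length(z) > 1) min(diff(z)) else 1
  idx <- findInterval(depth, c(z - dz / 2, z[length(z)] + dz / 2),
                      rightmost.closed = TRUE)
  out <- rep(NA_real_, length(z))
  good <- idx >= 1 & idx <= length(z) & is.finite(value)
  if (any(good)) {
    agg <- tapply(value[good], idx[good], mean)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Correct daytime fluorescence quenching with backscatter
#'
#' Non-photochemical quenching suppresses daytime chlorophyll fluorescence
#' near the surface. For each daytime profile, above the deepest depth where
#' PAR still exceeds `par_threshold`, chlorophyll is replaced by optical
#' backscatter scaled by that profile's chlorophyll-to-backscatter ratio
#' just below the quenched layer. The correction never reduces daytime
#' chlorophyll, and nighttime profiles are returned unchanged.
#'
#' @param chl,par,bbp depth x time matrices on a common grid.
#' @param time time axis (d); with `hour0` it yields the day/night mask
#'   (day = 06:00-18:00 local).
#' @param hour0 local clock hour at t = 0.
#' @param par_threshold quenching PAR threshold
#'   (umol photons m^-2 s^-1).
#' @param ref_cells number of cells just below the quenched layer used for
#'   the scaling ratio.
#' @param bbp_dark sensor dark offset (m^-1 sr^-1) subtracted before
#'   scaling, so cells without particles are not inflated; same
#'   calibration constant as the turbidity dark offset.
#' @param bbp_floor smallest particle backscatter (m^-1 sr^-1) accepted in
#'   the scaling layer; below it (sensor-noise level) the profile is left
#'   unchanged and flagged, since the chlorophyll:backscatter ratio would
#'   be a ratio of noise.
#' @return list with `chl` (corrected matrix) and `flag` (1 where the
#'   scaling layer had no usable backscatter and the cell was left as-is).
#' @export
correct_npq <- function(chl, par, bbp, time, hour0 = 12,
                        par_threshold = 100, ref_cells = 3,
                        bbp_dark = 0.001, bbp_floor = 1e-4) {
  stopifnot(all(dim(chl) == dim(par)), all(dim(chl) == dim(bbp)))
  out <- chl
  flag <- matrix(0L, nrow(chl), ncol(chl))
  day <- is_daytime(time, hour0)
  for (k in which(day)) {
    lit <- which(par[, k] > par_threshold)
    if (!length(lit)) next
    zq <- max(lit)                       # deepest quenching-lit cell
    ref <- seq(zq + 1L, min(zq + ref_cells, nrow(chl)))
    if (zq >= nrow(chl) || !length(ref)) { flag[seq_len(zq), k] <- 1L; next }
    # particle signal only: remove the dark offset so cells with no
    # chlorophyll are not inflated by the sensor dark count
    b0 <- bbp_dark
    bref <- mean(bbp[ref, k], na.rm = TRUE) - b0
    if (!is.finite(bref) || bref <= bbp_floor) {
      flag[seq_len(zq), k] <- 1L; next
    }
    ratio <- mean(chl[ref, k], na.rm = TRUE) / bref
    rows <- seq_len(zq)
    out[rows, k] <- pmax(chl[rows, k], (bbp[rows, k] - b0) * ratio)
  }
  list(chl = out, flag = flag)
}

#' Photosynthetically available radiation from irradiance channels
#'
#' PAR is taken as a weighted sum of the downwelling irradiance channels
#' (relative units). Weights are normalised to sum to one; at cells where
#' some channels are missing, the remaining channels are renormalised, and
#' cells with no channel at all are NA.
#'
#' @param channels list of depth x time matrices (one per channel).
#' @param weights channel weights (default equal).
#' @return PAR matrix.
#' @examples
#' compute_par(list(matrix(1), matrix(3)), weights = c(0.25, 0.75))
#' @export
compute_par <- function(channels, weights = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1)
  k <- length(channels)
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights >= 0), sum(weights) > 0)
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    m <- channels[[i]]
    ok <- is.finite(m)
    mm <- m; mm[!ok] <- 0
    num <- num + weights[i] * mm
    den <- den + weights[i] * ok
  }
  par <- num / den
  par[den == 0] <- NA_real_
  par
}

#' Near-surface PAR series
#'
#' Extracts the PAR time series at the grid cell nearest the reference
#' depth (default 2 m), the conventional "near-surface" light record.
#'
#' @param par depth x time PAR matrix.
#' @param z depth axis (m).
#' @param depth reference depth (m).
#' @return numeric time series.
#' @export
near_surface_par <- function(par, z, depth = 2) {
  par[which.min(abs(z - depth)), ]
}

#' Euphotic depth (1% light level) of a PAR profile
#'
#' The shallowest depth at which PAR falls below `fraction` (default 1%) of
#' its value at `ref_depth`. Interpolation between grid cells is linear in
#' log(PAR), which is exact for exponential light decay. If PAR never falls
#' below the threshold within the grid the bottom of the grid is returned
#' with an `unresolved` flag.
#'
#' @param par PAR profile (vector) or depth x time matrix.
#' @param z depth axis (m).
#' @param fraction light fraction defining the euphotic depth.
#' @param ref_depth reference depth (m) for the surface value.
#' @return for a vector: list(`depth`, `flag`); for a matrix: list of
#'   vectors `depth` and `flag` per time step. Flag 1 = unresolved.
#' @examples
#' z <- 0:100
#' euphotic_depth(100 * exp(-0.3 * z), z)$depth   # ln(100)/0.3
#' @export
euphotic_depth <- function(par, z, fraction = 0.01, ref_depth = 0) {
  if (is.matrix(par)) {
    res <- apply(par, 2L, euphotic_depth, z = z, fraction = fraction,
                 ref_depth = ref_depth)
    return(list(depth = vapply(res, `[[`, numeric(1), "depth"),
                flag = vapply(res, `[[`, integer(1), "flag")))
  }
  ref <- stats::approx(z, par, xout = ref_depth, rule = 2)$y
  if (!is.finite(ref) || ref <= 0)
    return(list(depth = NA_real_, flag = 1L))
  target <- fraction * ref
  below <- which(par < target)
  if (!length(below))
    return(list(depth = max(z), flag = 1L))
  i <- min(below)
  if (i == 1L) return(list(depth = z[1], flag = 0L))
  p1 <- par[i - 1L]; p2 <- par[i]
  d <- if (p1 > 0 && p2 > 0)
    (log(p1) - log(target)) / (log(p1) - log(p2))
  else (p1 - target) / (p1 - p2)
  list(depth = z[i - 1L] + d * (z[i] - z[i - 1L]), flag = 0L)
}

#' Turbidity proxy from optical backscatter
#'
#' Affine scaling of 532-nm backscatter: `gain * (bbp - dark)`, clipped at
#' zero (clipped cells are flagged).
#'
#' @param bbp backscatter (m^-1 sr^-1), vector or matrix.
#' @param gain,dark calibration gain and dark offset.
#' @return list with `turbidity` and `flag` (1 where clipped).
#' @examples
#' estimate_turbidity(0.004, gain = 200, dark = 0.001)$turbidity  # 0.6
#' @export
estimate_turbidity <- function(bbp, gain = 200, dark = 0.001) {
  turb <- gain * (bbp - dark)
  flag <- (turb < 0) * 1L
  turb[turb < 0] <- 0
  list(turbidity = turb, flag = flag)
}

#' Preprocess a raw profile grid
#'
#' Runs the full sensor chain on a [profile_grid()]: per-profile nitrate
#' quality control, PAR from the irradiance channels, quenching correction
#' of chlorophyll fluorescence, and the turbidity proxy. Profiles whose
#' nitrate is entirely flagged are marked unusable.
#'
#' @param grid a [profile_grid()] with variables `nitrate`, `chl`, `bbp`
#'   and irradiance channels `ed1..edK` (or `par`).
#' @param detection_limit,despike_window,mad_factor see [qc_nitrate()].
#' @param par_weights see [compute_par()].
#' @param par_threshold see [correct_npq()].
#' @param turb_gain,turb_dark see [estimate_turbidity()].
#' @return a `profile_grid` with cleaned `nitrate`, corrected `chl`, added
#'   `par` and `turbidity`, flag matrices, and an attribute
#'   `profile_usable` (logical per time step).
#' @export
preprocess_profiles <- function(grid, detection_limit = 0.5,
                                despike_window = 5, mad_factor = 5,
                                par_weights = NULL, par_threshold = 100,
                                turb_gain = 200, turb_dark = 0.001) {
  vars <- grid$vars
  flags <- grid$flags
  ch <- vars[grep("^ed[0-9]+$", names(vars))]
  if (length(ch)) vars$par <- compute_par(ch, par_weights)
  if (is.null(vars$par)) stop("no irradiance channels and no 'par' variable")

  nflag <- matrix(0L, length(grid$z), length(grid$time))
  for (k in seq_along(grid$time)) {
    q <- qc_nitrate(vars$nitrate[, k], window = despike_window,
                    detection_limit = detection_limit,
                    mad_factor = mad_factor)
    vars$nitrate[, k] <- q$value
    nflag[, k] <- q$flag
  }
  usable <- colSums(nflag != 0L) < length(grid$z)

  npq <- correct_npq(vars$chl, vars$par, vars$bbp, grid$time,
                     hour0 = grid$hour0, par_threshold = par_threshold,
                     bbp_dark = turb_dark)
  vars$chl <- npq$chl
  tb <- estimate_turbidity(vars$bbp, gain = turb_gain, dark = turb_dark)
  vars$turbidity <- tb$turbidity

  flags$nitrate <- nflag
  flags$chl <- npq$flag
  flags$turbidity <- tb$flag
  out <- profile_grid(grid$z, grid$time, vars, hour0 = grid$hour0,
                      flags = flags)
  attr(out, "profile_usable") <- usable
  attr(out, "detection_limit") <- detection_limit
  out
}
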