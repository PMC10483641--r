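#' Nitrate-specific rate of change from observations of one water mass
#'
#' Fits the exponential model N(t + dt) = N(t) exp(r dt) to nitrate
#' observations of a single water mass. With exactly two points the rate is
#' the closed form `r = log(n2/n1) / dt` and its standard error follows the
#' first-order delta method,
#' `se_r = sqrt((se1/n1)^2 + (se2/n2)^2) / dt`. With more than two points
#' the rate is the least-squares slope of log(N) against time, with the
#' regression standard error.
#'
#' @param n nitrate observations (mmol m^-3), length >= 2.
#' @param t observation times (d).
#' @param se per-observation standard errors (only used for the two-point
#'   delta method; default 0).
#' @param detection_limit values at or below this are refused: a pair with
#'   an undetectable member is unusable, not a zero rate.
#' @return data.frame with `r` (d^-1), `se`, `t_mid`, `dt` (time span) and
#'   `n_obs`.
#' @examples
#' fit_rate(c(10, 5), c(0, 1))$r           # log(1/2)
#' fit_rate(8 * exp(-0.5 * (0:2)), 0:2)$r  # -0.5
#' @export
fit_rate <- function(n, t, se = NULL, detection_limit = 0.5) {
  stopifnot(length(n) == length(t), length(n) >= 2)
  if (any(n <= detection_limit))
    stop("nitrate at or below the detection limit: pair refused")
  if (is.null(se)) se <- rep(0, length(n))
  dt <- diff(range(t))
  if (dt <= 0) stop("observations must span a positive time interval")
  if (length(n) == 2L) {
    r <- log(n[2] / n[1]) / dt
    se_r <- sqrt((se[1] / n[1])^2 + (se[2] / n[2])^2) / dt
  } else {
    fit <- stats::lm(log(n) ~ t)
    r <- unname(stats::coef(fit)[2])
    se_r <- unname(sqrt(diag(stats::vcov(fit)))[2])
  }
  data.frame(r = r, se = se_r, t_mid = mean(range(t)), dt = dt,
             n_obs = length(n))
}

#' Rate estimates for every observation pair
#'
#' Applies [fit_rate()]'s two-point closed form to each row of an
#' [find_reappearance_pairs()] table (vectorised).
#'
#' @param pairs an `obs_pairs` data.frame.
#' @return data.frame: `density_bin`, `spice_bin`, `r`, `se`, `t_mid`,
#'   `dt`.
#' @export
fit_rates <- function(pairs) {
  if (!nrow(pairs))
    return(data.frame(density_bin = numeric(), spice_bin = numeric(),
                      r = numeric(), se = numeric(), t_mid = numeric(),
                      dt = numeric()))
  data.frame(density_bin = pairs$density_bin, spice_bin = pairs$spice_bin,
             r = log(pairs$n2 / pairs$n1) / pairs$dt,
             se = sqrt((pairs$se1 / pairs$n1)^2 +
                         (pairs$se2 / pairs$n2)^2) / pairs$dt,
             t_mid = (pairs$t1 + pairs$t2) / 2,
             dt = pairs$dt)
}

# Build, for one density bin, the weight matrix A (time windows x
# estimates) mapping pair-level rate estimates onto the uniform time grid.
# Each pair's rate is an average over its own interval [t1, t2], so it is
# assigned to every window that interval covers; overlapping estimates
# combine with inverse-variance weights (which correctly suppresses the
# very noisy short-interval pairs wherever a longer pair overlaps).
# Windows covered by no pair are linearly interpolated from the nearest
# covered windows up to gap_limit. Keeping the full linear map (not just
# the averaged rates) lets the standard errors of every downstream
# quantity be propagated through the same map instead of assuming window
# independence.
rate_weight_matrix <- function(t1, t2, se, time, gap_limit) {
  nt <- length(time)
  ne <- length(t1)
  dt <- if (nt > 1) time[2] - time[1] else 1
  A <- matrix(0, nt, ne)
  w <- 1 / pmax(se, 1e-8)^2
  for (j in seq_len(ne)) {
    k1 <- max(1L, min(nt, ceiling((t1[j] - time[1]) / dt - 1e-9) + 1L))
    k2 <- max(1L, min(nt, floor((t2[j] - time[1]) / dt + 1e-9) + 1L))
    if (k2 >= k1) A[k1:k2, j] <- A[k1:k2, j] + w[j]
  }
  rs <- rowSums(A)
  status <- integer(nt)                 # 0 observed, 1 interpolated, 2 none
  status[rs == 0] <- 2L
  A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  filled <- which(rs > 0)
  if (length(filled) >= 1L) {
    for (k in which(status == 2L)) {
      lo <- filled[filled < k]; hi <- filled[filled > k]
      if (length(lo) && length(hi)) {
        k1 <- max(lo); k2 <- min(hi)
        if ((time[k2] - time[k1]) <= gap_limit) {
          lam <- (time[k] - time[k1]) / (time[k2] - time[k1])
          A[k, ] <- (1 - lam) * A[k1, ] + lam * A[k2, ]
          status[k] <- 1L
        }
      }
    }
  }
  list(A = A, status = status)
}

#' Fit the biologically driven nitrate-loss field
#'
#' The central estimator. Starting from an isopycnal-coordinate grid it
#' (i) computes spice and extracts nitrate observation pairs at water-mass
#' reappearances, (ii) fits the nitrate-specific rate of change r for each
#' pair, (iii) grids the rates onto a uniform time axis per density bin
#' (inverse-variance averaging within windows, linear interpolation across
#' gaps up to `gap_limit` days), and (iv) temporally iterates the predicted
#' nitrate `N(t + dt) = N(t) exp(r dt)` from the first usable observation
#' in each bin. The volumetric loss rate is the temporal differentiation
#' `rho = -(N(t+dt) - N(t))/dt` (positive = loss) and the cumulative loss
#' `Nloss` is its running time integral. Standard errors of every quantity
#' are propagated to first order through the full linear map from
#' pair-level rate errors (plus the initial-nitrate error), rather than
#' assuming the gridded rate windows are independent.
#'
#' @param iso an [to_isopycnal()] grid with `nitrate`, `temperature` and
#'   `salinity`.
#' @param spice_bin,spice_origin,max_dt,merge_gap,nitrate_se see
#'   [find_reappearance_pairs()].
#' @param detection_limit nitrate detection limit (mmol m^-3); values at or
#'   below it never enter log-space fits.
#' @param dt uniform iteration interval (d); default the native grid step.
#' @param gap_limit longest gap (d) across which gridded rates are
#'   interpolated; longer gaps are flagged and excluded.
#' @param alpha,beta spice coefficients, see [compute_spice()].
#' @return object of class `"nloss_fit"`: pair table, rate estimates, and
#'   per (density bin x time) the gridded rate `r` and its SE, predicted
#'   nitrate `nhat`, loss rate `rho` (mmol N m^-3 d^-1), cumulative loss
#'   `nloss` (mmol N m^-3), all with SE matrices; plus `status` (0 rate
#'   observed, 1 interpolated, 2 missing), `mean_depth`, `sigma`, `time`.
#' @seealso [depth_integrate()], [summary.nloss_fit()],
#'   [predict.nloss_fit()]
#' @export
fit_nitrate_loss <- function(iso, spice_bin = 0.005, spice_origin = 0,
                             max_dt = 2, merge_gap = 2,
                             detection_limit = 0.5, nitrate_se = 0.3,
                             dt = NULL, gap_limit = 1,
                             alpha = 0.2, beta = 0.78) {
  if (is.null(iso$vars$temperature) || is.null(iso$vars$salinity))
    stop("isopycnal grid must carry 'temperature' and 'salinity'")
  sp <- compute_spice(iso$vars$temperature, iso$vars$salinity,
                      alpha = alpha, beta = beta)
  pairs <- find_reappearance_pairs(iso, sp, spice_bin = spice_bin,
                                   spice_origin = spice_origin,
                                   max_dt = max_dt, merge_gap = merge_gap,
                                   detection_limit = detection_limit,
                                   nitrate_se = nitrate_se)
  rates <- fit_rates(pairs)

  native <- if (length(iso$time) > 1) iso$time[2] - iso$time[1] else 1
  if (is.null(dt)) dt <- native
  time <- seq(min(iso$time), max(iso$time), by = dt)
  nt <- length(time)
  nb <- length(iso$sigma)

  r_grid <- se_r <- nhat <- se_nhat <- rho <- se_rho <-
    nloss <- se_nloss <- matrix(NA_real_, nb, nt)
  status <- matrix(2L, nb, nt)

  for (i in seq_len(nb)) {
    est <- rates[rates$density_bin == iso$sigma[i], ]
    if (!nrow(est)) next
    wm <- rate_weight_matrix(est$t_mid - est$dt / 2, est$t_mid + est$dt / 2,
                             est$se, time, gap_limit)
    A <- wm$A
    rr <- as.numeric(A %*% est$r)
    rr[wm$status == 2L] <- 0
    sr2 <- as.numeric(A^2 %*% est$se^2)
    status[i, ] <- wm$status
    r_grid[i, ] <- ifelse(wm$status == 2L, NA, rr)
    se_r[i, ] <- ifelse(wm$status == 2L, NA, sqrt(sr2))

    # initial nitrate: first valid observation above the detection limit
    obs <- iso$vars$nitrate[i, ]
    k0_obs <- which(iso$valid[i, ] & is.finite(obs) &
                      obs > detection_limit)
    if (!length(k0_obs)) next
    n0 <- obs[min(k0_obs)]
    se_n0 <- nitrate_se
    k0 <- max(1L, min(which(time >= iso$time[min(k0_obs)] - 1e-9), nt))
    # a water mass cannot be predicted to hold more nitrate than it was
    # ever observed to hold: cap the iteration at the bin's observed
    # maximum so interpolated positive rates cannot run away exponentially
    n_cap <- max(obs[iso$valid[i, ]], na.rm = TRUE)

    # iterate N(t+dt) = N(t) exp(r dt); log N is linear in the pair rates,
    # so the cumulative weight vector c_j = dt * sum_k A[k, j] gives the
    # exact first-order variance of log(nhat)
    nh <- numeric(nt); nh[] <- NA
    nh[k0] <- n0
    csum <- rep(0, nrow(est))
    vln_r <- numeric(nt)                 # var of log nhat from rates only
    if (k0 < nt) {
      # exp() of a noisy rate integral is mean-biased upward by
      # exp(var/2) (lognormal convexity); correct with the accumulated
      # log-variance so the predicted nitrate is mean-unbiased
      for (k in k0:(nt - 1L)) {
        csum <- csum + A[k, ] * dt
        vln_r[k + 1L] <- sum((csum * est$se)^2)
        adj <- exp(-(vln_r[k + 1L] - vln_r[k]) / 2)
        nh[k + 1L] <- min(nh[k] * exp(rr[k] * dt) * adj, n_cap)
      }
    }
    nhat[i, ] <- nh
    vln <- (se_n0 / n0)^2 + vln_r
    se_nhat[i, ] <- nh * sqrt(ifelse(is.na(nh), NA, vln))

    # temporal differentiation: rho positive = loss; cells with no rate
    # information carry no loss estimate (flag propagates)
    rh <- c(-(nh[-1] - nh[-nt]) / dt, 0)
    rh[is.na(nh) | wm$status == 2L] <- NA
    rho[i, ] <- rh
    ef <- exp(rr * dt)
    se_rho[i, ] <- sqrt((nh * ef)^2 * sr2 +
                          ((1 - ef) / dt)^2 * (nh * sqrt(vln))^2)
    # cumulative loss Nloss(t) = n0 - nhat(t); first-order variance
    nl <- n0 - nh
    nl[seq_len(k0)] <- ifelse(is.na(nh[seq_len(k0)]), NA, 0)
    nloss[i, ] <- nl
    se_nloss[i, ] <- sqrt(((n0 - nh) / n0)^2 * se_n0^2 + nh^2 * vln_r)
  }

  structure(list(pairs = pairs, rates = rates, sigma = iso$sigma,
                 time = time, dt = dt,
                 mean_depth = mean_isopycnal_depth(iso),
                 r = r_grid, r_se = se_r, nhat = nhat, nhat_se = se_nhat,
                 rho = rho, rho_se = se_rho, nloss = nloss,
                 nloss_se = se_nloss, status = status,
                 native_dz = iso$native_dz %||% 0,
                 params = list(spice_bin = spice_bin, max_dt = max_dt,
                               merge_gap = merge_gap,
                               detection_limit = detection_limit,
                               gap_limit = gap_limit, dt = dt),
                 call = match.call()),
            class = "nloss_fit")
}

#' @export
print.nloss_fit <- function(x, ...) {
  cat("Biologically driven nitrate loss fit (nloss_fit)\n")
  cat(sprintf("  %d pairs -> %d rate estimates on %d density bins, %d time steps\n",
              nrow(x$pairs), nrow(x$rates), length(x$sigma),
              length(x$time)))
  cat(sprintf("  max cumulative loss: %.2f mmol N m-3\n",
              suppressWarnings(max(x$nloss, na.rm = TRUE))))
  invisible(x)
}

#' Summarise a nitrate-loss fit
#'
#' @param object an [fit_nitrate_loss()] result.
#' @param zrange depth range (m) for the depth-integrated figures.
#' @param ... unused.
#' @return a `summary.nloss_fit` list: pair and rate counts, rate
#'   quantiles, modal loss rate, maximum cumulative loss, and the
#'   record-average depth-integrated loss rate with its SE.
#' @export
summary.nloss_fit <- function(object, zrange = c(0, 33), ...) {
  rr <- object$rates$r
  inlay <- is.finite(object$mean_depth) & object$mean_depth >= zrange[1] &
    object$mean_depth <= zrange[2]
  rho_lay <- object$rho[inlay, , drop = FALSE]
  rho_pos <- rho_lay[is.finite(rho_lay) & rho_lay > 0]
  integ <- depth_integrate(object, zmin = zrange[1], zmax = zrange[2],
                           what = "rho")
  ok <- !integ$flag & is.finite(integ$value)
  avg <- mean(integ$value[ok])
  avg_se <- sqrt(mean(integ$se[ok]^2) / sum(ok))
  structure(list(n_pairs = nrow(object$pairs),
                 n_rates = nrow(object$rates),
                 r_quantiles = stats::quantile(rr, c(.1, .5, .9),
                                               na.rm = TRUE),
                 modal_rho = hist_mode(rho_pos, 0.5),
                 max_nloss = suppressWarnings(max(object$nloss,
                                                  na.rm = TRUE)),
                 zrange = zrange,
                 mean_integrated_rate = avg,
                 mean_integrated_rate_se = avg_se),
            class = "summary.nloss_fit")
}

#' @export
print.summary.nloss_fit <- function(x, ...) {
  cat("Nitrate loss summary\n")
  cat(sprintf("  pairs: %d; rate estimates: %d\n", x$n_pairs, x$n_rates))
  cat(sprintf("  r quantiles (d-1): %s\n",
              paste(sprintf("%.3f", x$r_quantiles), collapse = " / ")))
  cat(sprintf("  modal loss rate: %.2f mmol N m-3 d-1; max Nloss: %.2f mmol N m-3\n",
              x$modal_rho, x$max_nloss))
  f <- convert_flux_units(x$mean_integrated_rate,
                          x$mean_integrated_rate_se)
  cat(sprintf("  mean %g-%g m integrated loss rate: %.1f +/- %.1f mmol N m-2 d-1 (%g +/- %g mg N m-2 d-1)\n",
              x$zrange[1], x$zrange[2], x$mean_integrated_rate,
              x$mean_integrated_rate_se, f$value, f$se))
  invisible(x)
}

#' @export
coef.nloss_fit <- function(object, ...) {
  out <- rowMeans(object$r, na.rm = TRUE)
  names(out) <- sprintf("%.3f", object$sigma)
  out
}

#' Predicted nitrate at new times
#'
#' @param object an `nloss_fit`.
#' @param newtime times (d) at which to evaluate the predicted nitrate;
#'   default the fit's own grid.
#' @param ... unused.
#' @return matrix (density bin x newtime) of predicted nitrate.
#' @export
predict.nloss_fit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) return(object$nhat)
  t(vapply(seq_along(object$sigma), function(i) {
    y <- object$nhat[i, ]
    if (all(is.na(y))) return(rep(NA_real_, length(newtime)))
    stats::approx(object$time, y, xout = newtime, rule = 2)$y
  }, numeric(length(newtime))))
}

#' @export
plot.nloss_fit <- function(x, what = c("nloss", "rho", "nhat"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  keep <- is.finite(x$mean_depth)
  graphics::image(x$time, x$mean_depth[keep], t(m[keep, , drop = FALSE]),
                  ylim = rev(range(x$mean_depth[keep])),
                  xlab = "time (d)", ylab = "mean isopycnal depth (m)",
                  main = what, ...)
  invisible(x)
}

#' Depth-integrate a loss field over mean isopycnal depth
#'
#' Trapezoidal integration of cumulative loss (`nloss`, mmol N m^-2) or
#' loss rate (`rho`, mmol N m^-2 d^-1) over the mean-isopycnal-depth axis,
#' within `zmin`-`zmax` (default 0-33 m). Standard errors combine in
#' quadrature through the trapezoid weights; density bins lying within one
#' native vertical grid cell of each other interpolate the same profiler
#' samples, so their errors are treated as fully correlated (summed
#' linearly within such blocks) and only the blocks combine in
#' quadrature. A time step with more than half of the depth range missing
#' is flagged.
#'
#' @param fit an [fit_nitrate_loss()] result.
#' @param zmin,zmax integration limits (m).
#' @param what `"nloss"` or `"rho"`.
#' @return data.frame of class `"integrated_series"`: `time`, `value`,
#'   `se`, `flag`.
#' @export
depth_integrate <- function(fit, zmin = 0, zmax = 33, what = "nloss") {
  m <- fit[[what]]
  se <- fit[[paste0(what, "_se")]]
  sel <- which(is.finite(fit$mean_depth) & fit$mean_depth >= zmin &
                 fit$mean_depth <= zmax)
  # bins with no usable nitrate at all are not part of the loss field
  sel <- sel[rowSums(is.finite(m[sel, , drop = FALSE])) > 0]
  sel <- sel[order(fit$mean_depth[sel])]
  zz <- fit$mean_depth[sel]
  nt <- length(fit$time)
  ddz <- fit$native_dz %||% 0
  if (!is.finite(ddz)) ddz <- 0
  value <- sev <- rep(NA_real_, nt)
  flag <- rep(TRUE, nt)
  if (length(sel) >= 2L) {
    for (k in seq_len(nt)) {
      y <- m[sel, k]; s <- se[sel, k]
      ok <- is.finite(y)
      if (mean(ok) <= 0.5 || sum(ok) < 2L) next
      w <- trapz_weights(zz[ok])
      value[k] <- sum(w * y[ok])
      zok <- zz[ok]
      blk <- cumsum(c(1, diff(zok) > ddz))
      ws <- w * ifelse(is.finite(s[ok]), s[ok], 0)
      sev[k] <- sqrt(sum(tapply(ws, blk, sum)^2))
      flag[k] <- FALSE
    }
  }
  out <- data.frame(time = fit$time, value = value, se = sev, flag = flag)
  attr(out, "zrange") <- c(zmin, zmax)
  attr(out, "what") <- what
  class(out) <- c("integrated_series", "data.frame")
  out
}

#' Convert a nitrogen flux from molar to mass units
#'
#' Multiplies by the molar mass of nitrogen (14.007 g mol^-1) and reports
#' to three significant figures; the SE converts identically.
#'
#' @param flux flux in mmol N m^-2 d^-1.
#' @param se optional standard error, converted the same way.
#' @return list with `value` and `se` in mg N m^-2 d^-1 (3 s.f.).
#' @examples
#' convert_flux_units(31, 4)  # 434 +/- 56.0 mg N m^-2 d^-1
#' @export
convert_flux_units <- function(flux, se = NULL) {
  list(value = signif(flux * 14.007, 3),
       se = if (is.null(se)) NULL else signif(se * 14.007, 3))
}

#' Convert a swimming speed from micrometres per second to metres per hour
#'
#' @param um_s speed in um s^-1.
#' @param digits significant figures of the result (default 2).
#' @return speed in m h^-1.
#' @examples
#' convert_speed_units(380)  # 1.4 m per hour
#' @export
convert_speed_units <- function(um_s, digits = 2) {
  signif(um_s * 3600 / 1e6, digits)
}
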