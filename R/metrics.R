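#' Depth-integrate a biomass proxy on the isopycnal grid
#'
#' Trapezoidal depth integral of a field (chlorophyll, turbidity, ...) per
#' time step over the mean-isopycnal-depth axis within `zmin`-`zmax`
#' (default 0-33 m). Time steps with more than half the depth range
#' missing are flagged.
#'
#' @param field bin x time matrix on the isopycnal grid, or the name of a
#'   variable in `iso`.
#' @param iso an [to_isopycnal()] grid (supplies the mean-depth axis).
#' @param zmin,zmax integration limits (m).
#' @return data.frame of class `"integrated_series"`: `time`, `value`
#'   (integrand units x m), `se` (NA), `flag`.
#' @export
integrate_biomass <- function(field, iso, zmin = 0, zmax = 33) {
  if (is.character(field)) field <- iso$vars[[field]]
  md <- mean_isopycnal_depth(iso)
  sel <- which(is.finite(md) & md >= zmin & md <= zmax)
  sel <- sel[order(md[sel])]
  nt <- length(iso$time)
  value <- rep(NA_real_, nt); flag <- rep(TRUE, nt)
  if (length(sel) >= 2L) {
    zz <- md[sel]
    for (k in seq_len(nt)) {
      y <- field[sel, k]
      ok <- is.finite(y)
      if (mean(ok) <= 0.5 || sum(ok) < 2L) next
      value[k] <- trapz(zz[ok], y[ok])
      flag[k] <- FALSE
    }
  }
  out <- data.frame(time = iso$time, value = value, se = NA_real_,
                    flag = flag)
  attr(out, "zrange") <- c(zmin, zmax)
  class(out) <- c("integrated_series", "data.frame")
  out
}

#' Correlation between nitrate loss and biomass gain
#'
#' Pearson correlation (with two-sided p-value) between the
#' depth-integrated nitrate loss series and the *increase* of a
#' depth-integrated biomass series. The increase is taken relative to the
#' window start (default) or as first differences.
#'
#' @param loss,biomass `integrated_series` (or data.frames with `time`,
#'   `value`, optionally `flag`) on a common time grid.
#' @param increase `"start"`: biomass minus its first unflagged value;
#'   `"diff"`: first differences of both series.
#' @param average `"none"` correlates the native-resolution series;
#'   `"daily"` first averages both series over whole days, removing the
#'   diel oscillation that the migrating layer induces in a fixed-range
#'   depth integral (layer mass crossing the integration boundary), which
#'   is migration, not growth.
#' @return list with `R`, `p`, `n`.
#' @export
correlate_gain_loss <- function(loss, biomass,
                                increase = c("start", "diff"),
                                average = c("none", "daily")) {
  increase <- match.arg(increase)
  average <- match.arg(average)
  stopifnot(nrow(loss) == nrow(biomass))
  ok <- is.finite(loss$value) & is.finite(biomass$value)
  if (!is.null(loss$flag)) ok <- ok & !loss$flag
  if (!is.null(biomass$flag)) ok <- ok & !biomass$flag
  x <- loss$value[ok]; y <- biomass$value[ok]
  if (average == "daily") {
    day <- floor(loss$time[ok])
    x <- as.numeric(tapply(x, day, mean))
    y <- as.numeric(tapply(y, day, mean))
  }
  if (increase == "start") y <- y - y[1]
  else { y <- diff(y); x <- diff(x) }
  if (length(x) < 3L) stop("fewer than 3 usable points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance series: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Track the descending chlorophyll layer and estimate its speed
#'
#' Per time step within the window, the layer depth is the
#' chlorophyll-weighted centroid over cells exceeding the profile's
#' `threshold_q` quantile (so the estimate is invariant to rescaling the
#' field). An ordinary least-squares fit of layer depth against time gives
#' the descent speed; positive = downward.
#'
#' @param iso an [to_isopycnal()] grid with `chl` (or supply `field`).
#' @param start time (d) of the descent start (e.g. the 18:00 trigger).
#' @param window_h length of the tracking window (hours).
#' @param threshold_q quantile defining layer membership per profile.
#' @param field optional bin x time matrix overriding `iso$vars$chl`.
#' @param min_points minimum usable track points.
#' @return object of class `"descent_track"`: `time`, `depth` (track),
#'   `speed_um_s`, `se_um_s`, `speed_m_d`, `window`.
#' @export
estimate_descent_speed <- function(iso, start, window_h = 10,
                                   threshold_q = 0.75, field = NULL,
                                   min_points = 5) {
  chl <- field %||% iso$vars$chl
  if (is.null(chl)) stop("no chlorophyll field to track")
  md <- mean_isopycnal_depth(iso)
  keep <- which(iso$time >= start & iso$time <= start + window_h / 24)
  track_t <- iso$time[keep]
  # density bins are unevenly spaced in depth: the centroid integral needs
  # each bin's depth thickness (the mean-depth Jacobian) as a weight
  thick <- rep(NA_real_, length(md))
  fin <- which(is.finite(md))
  if (length(fin) >= 2L) thick[fin] <- trapz_weights(md[fin])
  track_z <- vapply(keep, function(k) {
    y <- chl[, k]
    ok <- is.finite(y) & is.finite(md) & is.finite(thick)
    if (sum(ok) < 3L) return(NA_real_)
    thr <- stats::quantile(y[ok], threshold_q)
    sel <- ok & y >= thr
    sum(md[sel] * y[sel] * thick[sel]) / sum(y[sel] * thick[sel])
  }, numeric(1))
  use <- is.finite(track_z)
  if (sum(use) < min_points)
    stop("fewer than ", min_points, " usable track points")
  fit <- stats::lm(track_z[use] ~ track_t[use])
  slope_m_d <- unname(stats::coef(fit)[2])
  se_m_d <- unname(sqrt(diag(stats::vcov(fit)))[2])
  structure(list(time = track_t, depth = track_z,
                 speed_um_s = slope_m_d / 86400 * 1e6,
                 se_um_s = se_m_d / 86400 * 1e6,
                 speed_m_d = slope_m_d,
                 window = c(start, start + window_h / 24)),
            class = "descent_track")
}

#' @export
print.descent_track <- function(x, ...) {
  cat(sprintf("descent_track: %.0f +/- %.0f um s-1 (%.1f m d-1) over %.2f-%.2f d\n",
              x$speed_um_s, x$se_um_s, x$speed_m_d,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Nitrogen-to-chlorophyll ratio of the bloom
#'
#' Ratio of the window-total depth-integrated nitrate loss to the
#' window-total depth-integrated chlorophyll increase. In the default
#' `"molar_per_mass"` mode the units are mmol N per mg Chl; `"mass"`
#' multiplies by the molar mass of nitrogen to give mg N per mg Chl.
#'
#' @param nloss_total total depth-integrated nitrate loss over the window
#'   (mmol N m^-2).
#' @param chl_increase total depth-integrated chlorophyll increase over
#'   the same window (mg Chl m^-2); must be positive.
#' @param units `"molar_per_mass"` or `"mass"`.
#' @return list with `ratio` and `units`.
#' @examples
#' n_to_chl_ratio(10, 2)$ratio  # 5
#' @export
n_to_chl_ratio <- function(nloss_total, chl_increase,
                           units = c("molar_per_mass", "mass")) {
  units <- match.arg(units)
  if (!is.finite(chl_increase) || chl_increase <= 0)
    stop("non-positive chlorophyll increase: ratio refused")
  if (!is.finite(nloss_total) || nloss_total <= 0)
    stop("non-positive nitrate loss total: ratio refused")
  r <- nloss_total / chl_increase
  if (units == "mass") r <- r * 14.007
  list(ratio = r, units = units)
}
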