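#' Remap a profile grid onto uniform density bins
#'
#' Internal waves heave tracers up and down with the isopycnals; plotting
#' and differencing fields on density surfaces instead of depth surfaces
#' removes that apparent variability. Each profile is interpolated linearly
#' in density onto uniformly spaced sigma-theta bin centres (default
#' interval 0.02 kg m^-3); the profile's own depth is remapped the same
#' way, giving each bin's instantaneous depth.
#'
#' Weak density inversions (instrument noise) are reordered by sorting the
#' profile in density; profiles with inversions larger than
#' `max_inversion` are flagged unusable rather than sorted, as are profiles
#' with fewer than two valid density samples. Linear (not spline)
#' interpolation is used to avoid overshoot at the sharp nitracline.
#'
#' @param grid a [profile_grid()] with a `sigma_theta` variable.
#' @param bin_width density bin interval (kg m^-3).
#' @param bin_edges optional explicit bin edges (overrides `bin_width`).
#' @param vars variables to remap (default: all except `sigma_theta`).
#' @param max_inversion largest tolerated density inversion (kg m^-3).
#' @return object of class `"iso_grid"`: `sigma` (bin centres), `time`,
#'   `depth` (bin x time instantaneous depth), `vars` (remapped matrices),
#'   `valid` (bin x time logical; FALSE outside a profile's density range
#'   or for unusable profiles), `profile_ok`.
#' @seealso [mean_isopycnal_depth()]
#' @export
to_isopycnal <- function(grid, bin_width = 0.02, bin_edges = NULL,
                         vars = NULL, max_inversion = 0.05) {
  rho <- grid$vars$sigma_theta
  if (is.null(rho)) stop("grid has no 'sigma_theta' variable")
  if (is.null(vars))
    vars <- setdiff(names(grid$vars), "sigma_theta")
  nt <- length(grid$time)

  if (is.null(bin_edges)) {
    lo <- floor(min(rho, na.rm = TRUE) / bin_width) * bin_width
    hi <- ceiling(max(rho, na.rm = TRUE) / bin_width) * bin_width
    bin_edges <- seq(lo, hi, by = bin_width)
  }
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  nb <- length(centers)

  depth <- matrix(NA_real_, nb, nt)
  out <- stats::setNames(
    replicate(length(vars), matrix(NA_real_, nb, nt), simplify = FALSE),
    vars)
  profile_ok <- rep(TRUE, nt)
  usable_attr <- attr(grid, "profile_usable")

  for (k in seq_len(nt)) {
    r <- rho[, k]
    ok <- is.finite(r)
    if (sum(ok) < 2L ||
        (!is.null(usable_attr) && !usable_attr[k])) {
      profile_ok[k] <- FALSE; next
    }
    inv <- max(cummax(r[ok]) - r[ok])
    if (inv > max_inversion) { profile_ok[k] <- FALSE; next }
    ord <- order(r[ok])
    rs <- r[ok][ord]
    zs <- grid$z[ok][ord]
    depth[, k] <- stats::approx(rs, zs, xout = centers, ties = mean)$y
    for (v in vars) {
      ys <- grid$vars[[v]][ok, k][ord]
      out[[v]][, k] <- stats::approx(rs, ys, xout = centers, ties = mean)$y
    }
  }
  valid <- is.finite(depth)
  structure(list(sigma = centers, edges = bin_edges, time = grid$time,
                 hour0 = grid$hour0, depth = depth, vars = out,
                 valid = valid, profile_ok = profile_ok,
                 native_dz = if (length(grid$z) > 1) min(diff(grid$z)) else 1,
                 detection_limit = attr(grid, "detection_limit")),
            class = "iso_grid")
}

#' @export
print.iso_grid <- function(x, ...) {
  cat(sprintf("iso_grid: %d density bins (%.2f-%.2f kg m-3) x %d times\n",
              length(x$sigma), min(x$sigma), max(x$sigma), length(x$time)))
  cat(sprintf("  variables: %s\n", paste(names(x$vars), collapse = ", ")))
  cat(sprintf("  usable profiles: %d/%d; valid cells: %.1f%%\n",
              sum(x$profile_ok), length(x$time), 100 * mean(x$valid)))
  invisible(x)
}

#' Time-mean depth of each density bin
#'
#' The arithmetic mean over valid times of a bin's instantaneous
#' interpolated depth. This is the display and integration vertical axis:
#' fields on density bins are plotted and depth-integrated against the mean
#' depths of the isopycnals. Bins never observed are NA.
#'
#' @param iso an [to_isopycnal()] grid.
#' @param window optional time window (days, length 2) over which to
#'   average; default is the full record.
#' @return numeric vector of mean depths (m), one per density bin.
#' @export
mean_isopycnal_depth <- function(iso, window = NULL) {
  d <- iso$depth
  if (!is.null(window)) {
    keep <- iso$time >= window[1] & iso$time <= window[2]
    d <- d[, keep, drop = FALSE]
  }
  md <- rowMeans(d, na.rm = TRUE)
  md[!is.finite(md)] <- NA_real_
  md
}
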