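#' Spice (temperature-salinity water-mass variable)
#'
#' Water parcels lying on the same isopycnal are distinguished by their
#' spice: warm/salty water is "spicier" than cool/fresh water of the same
#' density. This implementation uses the linearized, density-compensated
#' combination `alpha * T + beta * S` (kg m^-3), with coefficients matching
#' the linear equation of state `d sigma = -alpha dT + beta dS`, so that
#' spice variations are orthogonal to density variations. The formulation
#' and coefficients are recorded as attributes of the result.
#'
#' @param temp,sal temperature (degC) and salinity matrices or vectors on a
#'   common (isopycnal) grid.
#' @param alpha,beta linear coefficients (kg m^-3 per degC, kg m^-3 per
#'   salinity unit).
#' @param t_ref,s_ref reference values subtracted before combining (only an
#'   additive offset; irrelevant once binning origins shift with it).
#' @return spice (kg m^-3), same shape as inputs, NA where either input is
#'   missing; attributes `formulation`, `alpha`, `beta`.
#' @export
compute_spice <- function(temp, sal, alpha = 0.2, beta = 0.78,
                          t_ref = 0, s_ref = 0) {
  sp <- alpha * (temp - t_ref) + beta * (sal - s_ref)
  sp[!is.finite(temp) | !is.finite(sal)] <- NA_real_
  attr(sp, "formulation") <- "linear"
  attr(sp, "alpha") <- alpha
  attr(sp, "beta") <- beta
  sp
}

#' Nitrate observation pairs from water-mass reappearances
#'
#' Oscillating along-isopycnal currents carry the same water parcels past
#' the mooring repeatedly. On each isopycnal, cells are labelled by spice
#' bin (default interval 0.005 kg m^-3); cells in the same spice bin on an
#' isopycnal are assumed to be the same water mass. Contiguous occurrences
#' of a water mass (allowing interruptions up to `merge_gap` grid steps)
#' are collapsed into single visits (time median, nitrate mean); each
#' consecutive visit pair yields one nitrate observation pair. Pairs
#' separated by more than `max_dt` days, or with either nitrate value at or
#' below the detection limit, are discarded.
#'
#' @param iso an [to_isopycnal()] grid containing `nitrate`.
#' @param spice spice matrix on the same grid (e.g. from [compute_spice()]).
#' @param spice_bin spice bin interval (kg m^-3).
#' @param spice_origin origin of the spice bin edges (kg m^-3).
#' @param max_dt maximum pair separation (days).
#' @param merge_gap occurrences of the same water mass separated by at most
#'   this many grid steps are merged into one visit.
#' @param detection_limit nitrate detection limit (mmol m^-3); visits at or
#'   below it never enter pairs.
#' @param nitrate_se fallback per-sample nitrate standard error used when a
#'   visit has a single sample (mmol m^-3).
#' @return data.frame of class `"obs_pairs"` with columns `density_bin`
#'   (sigma-theta bin centre), `spice_bin` (integer bin label), `t1`, `t2`,
#'   `dt` (d), `n1`, `n2` (mmol m^-3), `se1`, `se2`, `k1`, `k2` (samples
#'   per visit).
#' @export
find_reappearance_pairs <- function(iso, spice, spice_bin = 0.005,
                                    spice_origin = 0, max_dt = 2,
                                    merge_gap = 2, detection_limit = 0.5,
                                    nitrate_se = 0.3) {
  nitr <- iso$vars$nitrate
  if (is.null(nitr)) stop("isopycnal grid has no 'nitrate' variable")
  stopifnot(all(dim(spice) == dim(nitr)))
  res <- vector("list", length(iso$sigma))

  for (i in seq_along(iso$sigma)) {
    lab <- floor((spice[i, ] - spice_origin) / spice_bin)
    lab[!iso$valid[i, ] | !is.finite(nitr[i, ])] <- NA
    keys <- unique(lab[!is.na(lab)])
    if (!length(keys)) next
    rows <- list()
    for (L in keys) {
      idx <- which(!is.na(lab) & lab == L)
      if (!length(idx)) next
      # split occurrences into visits: gaps > merge_gap steps start new visit
      brk <- c(0L, which(diff(idx) > merge_gap + 1L), length(idx))
      nv <- length(brk) - 1L
      if (nv < 2L) next
      vt <- vn <- vse <- numeric(nv); vk <- integer(nv)
      for (j in seq_len(nv)) {
        ii <- idx[(brk[j] + 1L):brk[j + 1L]]
        vt[j] <- stats::median(iso$time[ii])
        vals <- nitr[i, ii]
        vn[j] <- mean(vals)
        vk[j] <- length(ii)
        vse[j] <- if (length(ii) > 1L) stats::sd(vals) / sqrt(length(ii))
                  else nitrate_se
        if (!is.finite(vse[j]) || vse[j] <= 0) vse[j] <- nitrate_se
      }
      j1 <- seq_len(nv - 1L); j2 <- j1 + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        density_bin = iso$sigma[i], spice_bin = L,
        t1 = vt[j1], t2 = vt[j2], dt = vt[j2] - vt[j1],
        n1 = vn[j1], n2 = vn[j2], se1 = vse[j1], se2 = vse[j2],
        k1 = vk[j1], k2 = vk[j2])
    }
    if (length(rows)) res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(density_bin = numeric(), spice_bin = numeric(),
                      t1 = numeric(), t2 = numeric(), dt = numeric(),
                      n1 = numeric(), n2 = numeric(), se1 = numeric(),
                      se2 = numeric(), k1 = integer(), k2 = integer())
  out <- out[out$dt > 0 & out$dt <= max_dt &
               out$n1 > detection_limit & out$n2 > detection_limit, ]
  rownames(out) <- NULL
  class(out) <- c("obs_pairs", "data.frame")
  out
}

#' @export
print.obs_pairs <- function(x, ...) {
  cat(sprintf("obs_pairs: %d nitrate pairs on %d isopycnals; dt %.2f-%.2f d\n",
              nrow(x), length(unique(x$density_bin)),
              if (nrow(x)) min(x$dt) else NA, if (nrow(x)) max(x$dt) else NA))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
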