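#' Nitrate-temperature probability density function
#'
#' Two-dimensional histogram of paired temperature and nitrate samples
#' (default 0.25 degC temperature bins, 1 mmol m^-3 nitrate bins), with
#' each temperature column normalised independently so that every nonempty
#' temperature bin's PDF sums to one over nitrate bins.
#'
#' @param temp,nitrate paired samples (vectors of equal length).
#' @param t_bin temperature bin width (degC).
#' @param n_bin nitrate bin width (mmol m^-3).
#' @return object of class `"tn_pdf"`: `t_edges`, `n_edges`, `t_centers`,
#'   `n_centers`, `pdf` (temperature bin x nitrate bin), `counts` per
#'   temperature bin.
#' @export
build_tn_pdf <- function(temp, nitrate, t_bin = 0.25, n_bin = 1) {
  ok <- is.finite(temp) & is.finite(nitrate)
  temp <- temp[ok]; nitrate <- nitrate[ok]
  if (!length(temp)) stop("no usable temperature-nitrate samples")
  t_edges <- seq(floor(min(temp) / t_bin) * t_bin,
                 ceiling(max(temp) / t_bin) * t_bin + t_bin / 2, by = t_bin)
  n_edges <- seq(floor(min(nitrate) / n_bin) * n_bin,
                 ceiling(max(nitrate) / n_bin) * n_bin + n_bin / 2,
                 by = n_bin)
  ti <- findInterval(temp, t_edges, rightmost.closed = TRUE)
  ni <- findInterval(nitrate, n_edges, rightmost.closed = TRUE)
  nb_t <- length(t_edges) - 1L; nb_n <- length(n_edges) - 1L
  counts2d <- matrix(0, nb_t, nb_n)
  for (j in seq_along(ti)) counts2d[ti[j], ni[j]] <- counts2d[ti[j], ni[j]] + 1
  counts <- rowSums(counts2d)
  pdf <- counts2d / ifelse(counts > 0, counts, NA)
  structure(list(t_edges = t_edges, n_edges = n_edges,
                 t_centers = (t_edges[-1] + t_edges[-length(t_edges)]) / 2,
                 n_centers = (n_edges[-1] + n_edges[-length(n_edges)]) / 2,
                 pdf = pdf, counts = counts),
            class = "tn_pdf")
}

#' @export
print.tn_pdf <- function(x, ...) {
  cat(sprintf("tn_pdf: %d temperature bins x %d nitrate bins, %d samples\n",
              length(x$t_centers), length(x$n_centers), sum(x$counts)))
  invisible(x)
}

#' Fit the climatological nitrate-temperature line
#'
#' Weighted least-squares fit of per-temperature-bin mean nitrate against
#' temperature-bin centres, restricted to temperatures below `cutoff`
#' (default 14 degC, the climatological nitracline isotherm); weights are
#' the per-bin sample counts. An alternative mode fits the per-bin modal
#' nitrate instead of the mean.
#'
#' @param pdf a [build_tn_pdf()] object.
#' @param cutoff upper temperature limit (degC) of the fit and of the
#'   line's validity.
#' @param mode `"mean"` (default) or `"mode"`: per-bin statistic fitted.
#' @return object of class `"climatology_fit"` with `slope`, `intercept`,
#'   their standard errors, and `cutoff`. `coef()` returns
#'   (intercept, slope); `predict()` evaluates the line clipped below at
#'   zero.
#' @export
fit_climatology_line <- function(pdf, cutoff = 14,
                                 mode = c("mean", "mode")) {
  mode <- match.arg(mode)
  use <- which(pdf$t_centers < cutoff & pdf$counts > 0)
  if (length(use) < 2L)
    stop("need at least two nonempty temperature bins below the cutoff")
  stat <- vapply(use, function(i) {
    p <- pdf$pdf[i, ]
    if (mode == "mean") sum(p * pdf$n_centers, na.rm = TRUE)
    else pdf$n_centers[which.max(p)]
  }, numeric(1))
  fit <- stats::lm(stat ~ pdf$t_centers[use], weights = pdf$counts[use])
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 intercept_se = unname(se[1]), slope_se = unname(se[2]),
                 cutoff = cutoff, mode = mode, n_bins = length(use)),
            class = "climatology_fit")
}

#' @export
print.climatology_fit <- function(x, ...) {
  cat(sprintf("climatology_fit: Nitrate = %.4g T + %.4f (T < %g degC), %d bins (%s mode)\n",
              x$slope, x$intercept, x$cutoff, x$n_bins, x$mode))
  invisible(x)
}

#' @export
coef.climatology_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @rdname fit_climatology_line
#' @param object a `climatology_fit`.
#' @param newdata temperatures (degC) at which to evaluate the line.
#' @param ... unused.
predict.climatology_fit <- function(object, newdata, ...) {
  pmax(0, object$intercept + object$slope * newdata)
}

#' Nitrate deficit relative to the climatological line
#'
#' For each observation with temperature inside the line's validity range
#' (T below the cutoff), the deficit is
#' `max(0, predicted(T) - N)`; predictions are clipped below at zero.
#' Observations with T at or above the cutoff get NA (the deficit is
#' undefined there, not zero) and are flagged.
#'
#' @param temp,nitrate observed pairs.
#' @param fit a [fit_climatology_line()] object.
#' @return list with `deficit` (mmol m^-3, NA outside validity) and `flag`
#'   (1 where undefined).
#' @examples
#' f <- structure(list(intercept = 80.94, slope = -5.9, cutoff = 14),
#'                class = "climatology_fit")
#' nitrate_deficit(12, 0, f)$deficit  # 10.14
#' @export
nitrate_deficit <- function(temp, nitrate, fit) {
  pred <- predict(fit, temp)
  deficit <- pmax(0, pred - nitrate)
  bad <- !is.finite(temp) | temp >= fit$cutoff
  deficit[bad] <- NA_real_
  list(deficit = deficit, flag = as.integer(bad))
}
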