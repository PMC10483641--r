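#' @keywords internal
#' @importFrom stats simulate coef predict
#' @importFrom utils head
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Cumulative trapezoidal integral along x (same length as x, starts at 0)
#' @noRd
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

#' Quadrature weights of the trapezoid rule on nodes x (for SE propagation)
#' @noRd
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Local clock hour for times in days since record start
#'
#' All "local time" logic (06:00/18:00 day-night boundaries, the 18:00 descent
#' trigger) runs through this helper; `hour0` is the local clock hour at t = 0.
#' @noRd
local_hour <- function(t_days, hour0 = 12) {
  (hour0 + t_days * 24) %% 24
}

#' Daytime mask: local hour in [06:00, 18:00)
#' @noRd
is_daytime <- function(t_days, hour0 = 12) {
  h <- local_hour(t_days, hour0)
  h >= 6 & h < 18
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Histogram mode of a numeric vector (bin width h), midpoint of densest bin
#' @noRd
hist_mode <- function(x, h) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  edges <- seq(floor(min(x) / h) * h, max(x) + h, by = h)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  i <- which.max(counts)
  (edges[i] + edges[i + 1L]) / 2
}
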