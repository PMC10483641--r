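#' Depth-time profile grid
#'
#' Container for gridded profiler data: a set of depth x time matrices on a
#' common cell-centered depth axis (m, positive downward) and time axis
#' (days since record start). Mirrors what a wave-powered profiler delivers
#' after gridding: roughly 1-m vertical and 15-min temporal resolution.
#'
#' @param z depth axis (m), cell centres.
#' @param time time axis (days since start).
#' @param vars named list of depth x time matrices.
#' @param hour0 local clock hour at t = 0.
#' @param flags optional named list of integer flag matrices (0 = good).
#' @return object of class `"profile_grid"`.
#' @export
profile_grid <- function(z, time, vars, hour0 = 12, flags = list()) {
  stopifnot(is.list(vars), length(vars) > 0, !is.null(names(vars)))
  for (v in names(vars)) {
    m <- vars[[v]]
    if (!is.matrix(m) || nrow(m) != length(z) || ncol(m) != length(time))
      stop("variable '", v, "' is not a depth x time matrix on the grid")
  }
  structure(list(z = z, time = time, hour0 = hour0,
                 vars = vars, flags = flags),
            class = "profile_grid")
}

#' @export
print.profile_grid <- function(x, ...) {
  cat(sprintf("profile_grid: %d depths (%.1f-%.1f m) x %d times (%.2f-%.2f d)\n",
              length(x$z), min(x$z), max(x$z),
              length(x$time), min(x$time), max(x$time)))
  cat("  variables:", paste(names(x$vars), collapse = ", "), "\n")
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname profile_grid
#' @param x a `profile_grid`.
#' @param var variable to display.
#' @param ... passed to [graphics::image()].
plot.profile_grid <- function(x, var = names(x$vars)[1], ...) {
  graphics::image(x$time, x$z, t(x$vars[[var]]),
                  ylim = rev(range(x$z)), xlab = "time (d)",
                  ylab = "depth (m)", main = var, ...)
  invisible(x)
}

# --- plain-text interchange -------------------------------------------------

#' Write / read a profile grid as CSV files
#'
#' One `axes.csv` file (depth, time, local-time offset) plus one matrix CSV
#' per variable (rows = depths, columns = times). Round-trips exactly at
#' full double precision.
#'
#' @param grid a [profile_grid()].
#' @param dir output directory (created if needed).
#' @return `write_grid_csv` returns `dir` invisibly; `read_grid_csv` returns
#'   the reconstructed `profile_grid`.
#' @export
write_grid_csv <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(axis = c(rep("z", length(grid$z)),
                                       rep("time", length(grid$time)),
                                       "hour0"),
                              value = c(grid$z, grid$time, grid$hour0)),
                   file.path(dir, "axes.csv"), row.names = FALSE)
  for (v in names(grid$vars))
    utils::write.table(format(grid$vars[[v]], digits = 17, trim = TRUE),
                       file.path(dir, paste0(v, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  for (v in names(grid$flags))
    utils::write.table(grid$flags[[v]],
                       file.path(dir, paste0("flag_", v, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(dir) {
  ax <- utils::read.csv(file.path(dir, "axes.csv"))
  z <- ax$value[ax$axis == "z"]
  time <- ax$value[ax$axis == "time"]
  hour0 <- ax$value[ax$axis == "hour0"]
  files <- list.files(dir, pattern = "\\.csv$")
  files <- setdiff(files, "axes.csv")
  vars <- list(); flags <- list()
  for (f in files) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = ","))
    dimnames(m) <- NULL
    nm <- sub("\\.csv$", "", f)
    if (startsWith(nm, "flag_")) flags[[sub("^flag_", "", nm)]] <- m
    else vars[[nm]] <- m
  }
  profile_grid(z, time, vars, hour0 = hour0, flags = flags)
}

#' Write a profile grid to NetCDF (optional)
#'
#' Requires the `ncdf4` package. Dimensions are `depth` and `time` in CF
#' style; one float variable per field.
#'
#' @param grid a [profile_grid()].
#' @param path output `.nc` file.
#' @export
write_grid_ncdf <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the 'ncdf4' package is required for NetCDF output; ",
         "use write_grid_csv() otherwise")
  dimz <- ncdf4::ncdim_def("depth", "m", grid$z)
  dimt <- ncdf4::ncdim_def("time", "days since start", grid$time)
  vars <- lapply(names(grid$vars), function(v)
    ncdf4::ncvar_def(v, "", list(dimz, dimt), prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[i]], grid$vars[[names(grid$vars)[i]]])
  ncdf4::ncatt_put(nc, 0, "hour0_local", grid$hour0)
  invisible(path)
}
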