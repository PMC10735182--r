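#' Trajectory container
#'
#' The common currency between the exact simulators, the rate-law
#' approximants and the estimators: a strictly increasing time grid plus one
#' or more named concentration series aligned to it. Off-grid evaluation uses
#' cubic-spline interpolation.
#'
#' @param times strictly increasing numeric grid (h).
#' @param ... named numeric series, each the same length as `times`, or a
#'   single named list of such series.
#' @return An object of class `ets_trajectory`.
#' @export
trajectory <- function(times, ...) {
  series <- list(...)
  if (length(series) == 1L && is.list(series[[1L]]) &&
      !is.numeric(series[[1L]])) {
    series <- series[[1L]]
  }
  stopifnot(is.numeric(times), length(times) >= 2L, all(diff(times) > 0),
            length(series) >= 1L, !is.null(names(series)),
            all(nzchar(names(series))))
  for (nm in names(series)) {
    if (length(series[[nm]]) != length(times)) {
      stop("series '", nm, "' length does not match time grid")
    }
  }
  structure(list(times = times, series = series), class = "ets_trajectory")
}

#' @export
print.ets_trajectory <- function(x, ...) {
  cat("<ets_trajectory> ", length(x$times), " points on [",
      format(x$times[1L]), ", ", format(x$times[length(x$times)]), "] h; series: ",
      paste(names(x$series), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ets_trajectory <- function(x, ...) {
  do.call(data.frame, c(list(time = x$times), x$series))
}

#' Interpolating accessor for one trajectory series
#'
#' @param traj an `ets_trajectory`.
#' @param name series name; defaults to the first series.
#' @param periodic treat the series as one cycle of a periodic orbit.
#' @return A function of time.
#' @export
trajectory_fun <- function(traj, name = NULL, periodic = FALSE) {
  stopifnot(inherits(traj, "ets_trajectory"))
  name <- name %||% names(traj$series)[1L]
  y <- traj$series[[name]]
  if (is.null(y)) stop("no series named '", name, "'")
  if (periodic) {
    y2 <- y
    y2[length(y2)] <- y2[1L]
    sf <- stats::splinefun(traj$times, y2, method = "periodic")
  } else {
    sf <- stats::splinefun(traj$times, y, method = "natural")
  }
  function(t) pmax(sf(t), 0)
}

#' Discrepancy between a reference and an approximating trajectory
#'
#' Interpolates the approximation onto the part of the reference grid covered
#' by both trajectories and reports an error metric: root-mean-square error,
#' maximum absolute error, or the ratio of relative amplitudes
#' (approx / reference).
#'
#' @param reference,approx `ets_trajectory` objects.
#' @param metric one of "rmse", "max_abs", "relative_amplitude_ratio".
#' @param series series name compared (must exist in both); defaults to the
#'   first series of the reference.
#' @export
trajectory_error <- function(reference, approx,
                             metric = c("rmse", "max_abs",
                                        "relative_amplitude_ratio"),
                             series = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(reference, "ets_trajectory"),
            inherits(approx, "ets_trajectory"))
  series <- series %||% names(reference$series)[1L]
  lo <- max(reference$times[1L], approx$times[1L])
  hi <- min(reference$times[length(reference$times)],
            approx$times[length(approx$times)])
  keep <- reference$times >= lo & reference$times <= hi
  if (!any(keep)) stop("trajectories have no overlapping time domain")
  tt <- reference$times[keep]
  ref <- reference$series[[series]][keep]
  app <- trajectory_fun(approx, series)(tt)
  switch(metric,
    rmse = sqrt(mean((app - ref)^2)),
    max_abs = max(abs(app - ref)),
    relative_amplitude_ratio = relative_amplitude(app) / relative_amplitude(ref)
  )
}

#' Write / read a trajectory as CSV
#'
#' Column layout: `time`, then one column per series.
#'
#' @param traj an `ets_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "time") stop("first CSV column must be 'time'")
  trajectory(df$time, as.list(df[-1L]))
}
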