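#' Time-varying concentration drivers
#'
#' A driver is a prescribed total-concentration function of time, used as
#' \eqn{A(t)}, \eqn{B(t)} or \eqn{A_{TF}(t)} in the rate laws and reference
#' simulators. Drivers are either closed-form sinusoids or interpolated
#' tabulated series; both evaluate at arbitrary times within their domain and
#' are guaranteed non-negative (interpolation undershoot is clamped to zero).
#'
#' @param baseline mean level (concentration units); must be >= amplitude so
#'   the driver never goes negative.
#' @param amplitude oscillation amplitude (same units as baseline).
#' @param period oscillation period in hours (default 24, a circadian cycle).
#' @param phase time at which the sinusoid crosses its baseline going up (h).
#' @return An object of class `ets_driver`: callable as `driver_value(d, t)`.
#' @examples
#' d <- driver_sinusoid(1, 0.5, period = 24)
#' driver_value(d, c(0, 6, 12))
#' @export
driver_sinusoid <- function(baseline, amplitude, period = 24, phase = 0) {
  stopifnot(is.finite(baseline), is.finite(amplitude), period > 0)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (amplitude > baseline) {
    stop("amplitude must not exceed baseline (driver would go negative)")
  }
  f <- function(t) baseline + amplitude * sin(2 * pi * (t - phase) / period)
  new_driver(f, domain = c(-Inf, Inf),
             meta = list(kind = "sinusoid", baseline = baseline,
                         amplitude = amplitude, period = period, phase = phase))
}

#' @rdname driver_sinusoid
#' @param value constant concentration level.
#' @export
driver_constant <- function(value) {
  stopifnot(is.finite(value), value >= 0)
  f <- function(t) rep_len(value, length(t))
  new_driver(f, domain = c(-Inf, Inf),
             meta = list(kind = "constant", value = value))
}

#' Driver from a tabulated concentration series
#'
#' Interpolates a discrete time series with a cubic spline (the package-wide
#' evaluation contract for tabulated data). Negative interpolation artifacts
#' are clamped to zero. With `periodic = TRUE` the series is treated as one
#' cycle of a limit-cycle orbit and extended periodically, which makes delayed
#' evaluation times before the tabulated window well defined.
#'
#' @param times strictly increasing time grid (h).
#' @param values concentrations at `times`; must be non-negative.
#' @param periodic extend periodically with period `times[n] - times[1]`?
#' @return An `ets_driver`.
#' @export
driver_series <- function(times, values, periodic = FALSE) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(diff(times) > 0))
  if (any(values < 0)) stop("driver values must be non-negative")
  if (periodic) {
    v <- values
    v[length(v)] <- v[1L]  # periodic spline closes the orbit
    sf <- stats::splinefun(times, v, method = "periodic")
    dom <- c(-Inf, Inf)
  } else {
    sf <- stats::splinefun(times, values, method = "natural")
    dom <- range(times)
  }
  f <- function(t) pmax(sf(t), 0)
  new_driver(f, domain = dom,
             meta = list(kind = if (periodic) "periodic_series" else "series",
                         n = length(times)))
}

new_driver <- function(f, domain, meta = list()) {
  structure(list(f = f, domain = domain, meta = meta), class = "ets_driver")
}

#' Evaluate a driver
#'
#' Evaluation outside the driver's domain uses a constant-history rule on the
#' left (the value at the domain start), matching simulations that begin from
#' a steady state; evaluation beyond the right edge is an error.
#'
#' @param d an `ets_driver`.
#' @param t time or vector of times (h).
#' @export
driver_value <- function(d, t) {
  stopifnot(inherits(d, "ets_driver"))
  t <- pmax(t, d$domain[1L])
  if (any(t > d$domain[2L])) stop("driver evaluated beyond its domain")
  d$f(t)
}

#' @export
print.ets_driver <- function(x, ...) {
  cat("<ets_driver:", x$meta$kind %||% "custom", ">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_driver <- function(x) {
  if (inherits(x, "ets_driver")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(driver_constant(x))
  if (is.function(x)) return(new_driver(function(t) pmax(x(t), 0),
                                        domain = c(-Inf, Inf),
                                        meta = list(kind = "function")))
  stop("cannot interpret object as a driver")
}
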