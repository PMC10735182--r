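#' Kinetic parameters of a pairwise binding interaction
#'
#' Bundles the association rate \eqn{k_a} and the effective complex decay
#' rate \eqn{k_\delta} of a reversible pair interaction, together with the
#' derived dissociation-scale constant \eqn{K = k_\delta / k_a}. The decay
#' rate lumps every first-order event that lowers the complex level
#' (dissociation, conversion, translocation, dilution); only the sum enters
#' the rate laws. Exactly two of `k_a`, `k_delta`, `K` must be given.
#'
#' @param k_a association rate (concentration\eqn{^{-1}} h\eqn{^{-1}}).
#' @param k_delta effective decay rate of the complex (h\eqn{^{-1}}).
#' @param K dissociation-scale constant \eqn{k_\delta/k_a} (concentration).
#' @return An object of class `binding_params` with fields `k_a`, `k_delta`, `K`.
#' @examples
#' binding_params(k_a = 10, k_delta = 1)      # K = 0.1
#' binding_params(K = 0.5, k_delta = 2)       # k_a = 4
#' @export
binding_params <- function(k_a = NULL, k_delta = NULL, K = NULL) {
  given <- !vapply(list(k_a, k_delta, K), is.null, logical(1))
  if (sum(given) != 2L) stop("give exactly two of k_a, k_delta, K")
  if (is.null(K)) K <- k_delta / k_a
  if (is.null(k_a)) k_a <- k_delta / K
  if (is.null(k_delta)) k_delta <- k_a * K
  stopifnot(k_a > 0, k_delta > 0, K > 0)
  structure(list(k_a = k_a, k_delta = k_delta, K = K),
            class = "binding_params")
}

#' Kinetic parameters of a single-site TF-DNA interaction
#'
#' As [binding_params()] but for a transcription factor binding one DNA site:
#' `k_a` is the TF-DNA binding rate, `k_delta` the unbinding rate, and `V`
#' the nuclear volume, so that `1/V` is the concentration contributed by one
#' DNA copy and `V * C` is an occupancy probability.
#'
#' @inheritParams binding_params
#' @param V nuclear volume (inverse concentration per site).
#' @export
tf_params <- function(k_a = NULL, k_delta = NULL, K = NULL, V = 1) {
  bp <- binding_params(k_a = k_a, k_delta = k_delta, K = K)
  stopifnot(V > 0)
  structure(c(unclass(bp), list(V = V)), class = c("tf_params", "binding_params"))
}

check_conc <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  invisible(TRUE)
}

#' Discriminant factor of the total-QSSA complex concentration
#'
#' \deqn{\Delta_{tQ} = \sqrt{1 + 2(A+B)/K + ((A-B)/K)^2} \ge 1.}
#' This is the square-rooted discriminant of the complex quadratic,
#' normalised so that \eqn{\Delta_{tQ} = 1} when no molecules are present;
#' \eqn{1/(k_\delta \Delta_{tQ})} is the effective relaxation time of complex
#' formation (see [effective_delay_pp()]).
#'
#' @param A,B total concentrations of the two binding partners (vectorised).
#' @param params a [binding_params()].
#' @export
delta_tq <- function(A, B, params) {
  check_conc(A, B)
  K <- params$K
  sqrt(1 + 2 * (A + B) / K + ((A - B) / K)^2)
}

#' Total-QSSA (tQSSA) complex concentration
#'
#' The quasi-steady-state complex level in total concentrations: the smaller
#' root of \eqn{k_a (A - C)(B - C) = k_\delta C}. Computed in the
#' cancellation-free form \eqn{C_{tQ} = 2AB / (K + A + B + K\Delta_{tQ})},
#' which remains accurate in the titration limit \eqn{K \to 0} where the
#' textbook subtractive form loses all precision.
#'
#' @inheritParams delta_tq
#' @export
complex_tqssa <- function(A, B, params) {
  check_conc(A, B)
  K <- params$K
  denom <- K + A + B + K * delta_tq(A, B, params)
  out <- 2 * A * B / denom
  out[A == 0 | B == 0] <- 0
  out
}

#' Pade-approximant (sQSSA) complex concentration
#'
#' \eqn{A B / (K + A + B)}: the low-complex limit of the tQSSA, valid when
#' \eqn{B \ll K + A} (or symmetrically \eqn{A \ll K + B}). Returns 0 when
#' \eqn{K + A + B = 0}.
#'
#' @inheritParams delta_tq
#' @export
complex_sqssa_pade <- function(A, B, params) {
  check_conc(A, B)
  denom <- params$K + A + B
  out <- ifelse(denom > 0, A * B / denom, 0)
  out
}

#' Michaelis-Menten complex concentration
#'
#' The familiar saturating form \eqn{S E_0 / (K + S)} for substrate
#' concentration `substrate` and total enzyme `enzyme_total`; `K` is the
#' Michaelis constant.
#'
#' @param substrate,enzyme_total concentrations (vectorised).
#' @param params a [binding_params()].
#' @export
complex_mm <- function(substrate, enzyme_total, params) {
  check_conc(substrate, enzyme_total)
  substrate * enzyme_total / (params$K + substrate)
}

#' Effective time delay of complex formation (protein-protein)
#'
#' \eqn{[k_\delta \Delta_{tQ}(t)]^{-1}}: the rigorously estimated relaxation
#' time of the complex towards its quasi-steady state. At most
#' \eqn{1/k_\delta} (attained with no molecules present) and decreasing in
#' the free-molecule concentration; satisfies the identity
#' \eqn{k_\delta^{-1} \{1 + K^{-1}[A + B - 2 C_{tQ}]\}^{-1}}.
#'
#' @inheritParams delta_tq
#' @return delay in hours.
#' @export
effective_delay_pp <- function(A, B, params) {
  1 / (params$k_delta * delta_tq(A, B, params))
}

#' ETS complex concentration (protein-protein)
#'
#' The effective time-delay scheme: the tQSSA evaluated at the delayed time
#' \eqn{t - [k_\delta \Delta_{tQ}(t)]^{-1}} (the delay computed from the
#' current totals), clamped so the complex never exceeds either current
#' total:
#' \deqn{C_\gamma(t) = \min\{ C_{tQ}(t - [k_\delta \Delta_{tQ}(t)]^{-1}),
#'   A(t), B(t) \}.}
#' For constant drivers this reduces exactly to the tQSSA, and it converges
#' to the tQSSA pointwise as \eqn{k_\delta \to \infty}.
#'
#' Delayed times that fall before a driver's domain use the driver's
#' constant-history rule (its value at the domain start), matching
#' simulations initialised at a steady state.
#'
#' @param driver_A,driver_B drivers (see [driver_sinusoid()]) for the total
#'   concentrations; constants and plain functions are also accepted.
#' @param t evaluation time(s) (h).
#' @param params a [binding_params()].
#' @export
complex_ets <- function(driver_A, driver_B, t, params) {
  driver_A <- as_driver(driver_A); driver_B <- as_driver(driver_B)
  A_now <- driver_value(driver_A, t)
  B_now <- driver_value(driver_B, t)
  tau <- effective_delay_pp(A_now, B_now, params)
  ts <- t - tau
  C_lag <- complex_tqssa(driver_value(driver_A, ts),
                         driver_value(driver_B, ts), params)
  pmin(C_lag, A_now, B_now)
}

#' QSSA mean occupancy for a single-site TF-DNA interaction
#'
#' The population-averaged bound-TF concentration from the chemical master
#' equation under the quasi-steady-state assumption:
#' \deqn{C_{TFQ} = \frac{A_{TF}}{V (K + A_{TF})}.}
#' Note the denominator is \eqn{K + A_{TF}}, not
#' \eqn{K + A_{TF} + V^{-1}}: the missing site-concentration term is a
#' genuine consequence of single-site stochasticity, which distinguishes this
#' law from a naive continuum limit.
#'
#' @param A_TF total transcription-factor concentration (vectorised).
#' @param tf a [tf_params()].
#' @return bound-site concentration; multiply by `V` for an occupancy
#'   probability in \[0, 1\].
#' @export
occupancy_qssa_tf <- function(A_TF, tf) {
  check_conc(A_TF)
  A_TF / (tf$V * (tf$K + A_TF))
}

#' Effective time delay of a TF-DNA interaction
#'
#' \eqn{k_\delta^{-1} K / (K + A_{TF})}: proportional to the quasi-steady-state
#' probability that the DNA site is unoccupied, and at most \eqn{1/k_\delta}.
#'
#' @inheritParams occupancy_qssa_tf
#' @export
effective_delay_tf <- function(A_TF, tf) {
  check_conc(A_TF)
  (1 / tf$k_delta) * tf$K / (tf$K + A_TF)
}

#' ETS mean occupancy for a single-site TF-DNA interaction
#'
#' The QSSA occupancy evaluated at the delayed time
#' \eqn{t - k_\delta^{-1} K / (K + A_{TF}(t))}; reduces to
#' [occupancy_qssa_tf()] for constant TF levels.
#'
#' @param driver_A_TF driver for the total TF concentration.
#' @param t evaluation time(s) (h).
#' @param tf a [tf_params()].
#' @export
occupancy_ets_tf <- function(driver_A_TF, t, tf) {
  driver_A_TF <- as_driver(driver_A_TF)
  A_now <- driver_value(driver_A_TF, t)
  ts <- t - effective_delay_tf(A_now, tf)
  occupancy_qssa_tf(driver_value(driver_A_TF, ts), tf)
}

#' Stochastic Michaelis-Menten law of Levine and Hwa
#'
#' \eqn{A B / (K + A + B - V^{-1})}, the finite-volume stochastic correction
#' of the Pade form. With \eqn{B = 1/V} (one DNA site) it reduces
#' algebraically to the TF-DNA QSSA occupancy, and as \eqn{V \to \infty} it
#' recovers the deterministic Pade approximant.
#'
#' @inheritParams delta_tq
#' @param V system volume (inverse concentration).
#' @export
levine_hwa_mm <- function(A, B, params, V) {
  check_conc(A, B)
  stopifnot(V > 0)
  denom <- params$K + A + B - 1 / V
  if (any(denom <= 0)) stop("non-positive denominator in Levine-Hwa form")
  A * B / denom
}
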