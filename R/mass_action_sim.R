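#' Exact mass-action dynamics of a pairwise complex
#'
#' Integrates the mass-action balance for the complex concentration
#' \deqn{dC/dt = k_a [A(t) - C][B(t) - C] - k_\delta C}
#' with prescribed total-concentration drivers, using LSODA with a maximum
#' step of 0.05 h (the reference step used throughout the package). This is
#' the exact dynamics against which the tQSSA and ETS approximants are
#' judged.
#'
#' @param driver_A,driver_B drivers for the total concentrations.
#' @param params a [binding_params()].
#' @param C0 initial complex concentration; must not exceed either total at
#'   the initial time.
#' @param times output grid (h).
#' @param atol,rtol,max_step solver controls.
#' @return An `ets_trajectory` with series `C`, `A`, `B`.
#' @export
simulate_binding_ode <- function(driver_A, driver_B, params, C0 = 0, times,
                                 atol = 1e-9, rtol = 1e-8, max_step = 0.05) {
  driver_A <- as_driver(driver_A); driver_B <- as_driver(driver_B)
  A0 <- driver_value(driver_A, times[1L])
  B0 <- driver_value(driver_B, times[1L])
  if (C0 < 0 || C0 > min(A0, B0) + 1e-12) {
    stop("C0 must lie in [0, min(A(t0), B(t0))]")
  }
  rhs <- function(t, y, p) {
    A <- driver_value(driver_A, t); B <- driver_value(driver_B, t)
    list(params$k_a * (A - y[1L]) * (B - y[1L]) - params$k_delta * y[1L])
  }
  sol <- suppressWarnings(
    deSolve::ode(y = c(C = C0), times = times, func = rhs, parms = NULL,
                 method = "lsoda", atol = atol, rtol = rtol,
                 hmax = max_step, maxsteps = 20000))
  if (attr(sol, "istate")[1L] < 0 || anyNA(sol[, "C"])) {
    # a totals decline that outruns complex decay makes C cross above
    # min(A, B), where the prescribed-totals model blows up in finite time
    stop("ODE solver failed (ill-posed driver/decay combination?); ",
         "last valid time ", signif(max(sol[!is.na(sol[, "C"]), 1L]), 6))
  }
  trajectory(times, C = as.numeric(sol[, "C"]),
             A = driver_value(driver_A, times),
             B = driver_value(driver_B, times))
}

#' Stochastic single-site TF-DNA binding (two-state chain ensemble)
#'
#' Simulates `n_cells` independent cells, each carrying one DNA site that
#' switches empty -> bound with propensity \eqn{k_a A_{TF}(t)} and
#' bound -> empty with propensity \eqn{k_\delta}, and returns the
#' population-averaged bound-site concentration (occupancy / V). The
#' time-varying chain is sampled on the output grid with the driver frozen
#' within each step and the exact two-state transition probabilities applied
#' per step, so the marginal law at the grid times is exact up to the
#' piecewise-constant driver approximation (use a grid step of at most
#' 0.05 h for rhythmic drivers).
#'
#' @param driver_A_TF driver for the total TF concentration.
#' @param tf a [tf_params()].
#' @param n_cells ensemble size (>= 1).
#' @param seed integer seed fixing the random stream; identical inputs and
#'   seed give identical output.
#' @param times output grid (h).
#' @param p0 initial occupancy probability of each site (default 0: empty).
#' @return An `ets_trajectory` with series `C_TF` (mean bound concentration)
#'   and `occupancy` (mean occupancy probability).
#' @export
simulate_tf_ctmc <- function(driver_A_TF, tf, n_cells, seed, times, p0 = 0) {
  driver_A_TF <- as_driver(driver_A_TF)
  stopifnot(n_cells >= 1L, length(times) >= 2L, all(diff(times) > 0),
            p0 >= 0, p0 <= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  state <- as.integer(stats::runif(n_cells) < p0)
  occ <- numeric(length(times))
  occ[1L] <- mean(state)
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    # freeze the driver at the step midpoint
    kon <- tf$k_a * driver_value(driver_A_TF, times[i] + dt / 2)
    lam <- kon + tf$k_delta
    pstat <- if (lam > 0) kon / lam else 0
    decay <- exp(-lam * dt)
    p_on <- pstat + (state - pstat) * decay  # exact 2-state conditional law
    state <- as.integer(stats::runif(n_cells) < p_on)
    occ[i + 1L] <- mean(state)
  }
  trajectory(times, C_TF = occ / tf$V, occupancy = occ)
}

#' Deterministic ensemble-mean TF-DNA occupancy (master-equation mean)
#'
#' For a single site with binding propensity \eqn{k_a A_{TF}(t)} from the
#' empty state, the ensemble-mean occupancy \eqn{p(t)} obeys the linear ODE
#' \eqn{dp/dt = k_a A_{TF}(t) (1 - p) - k_\delta p} exactly (the master
#' equation closes at first order). This gives the exact reference mean
#' without Monte-Carlo noise; [simulate_tf_ctmc()] is its stochastic
#' counterpart.
#'
#' @inheritParams simulate_tf_ctmc
#' @return An `ets_trajectory` with series `C_TF` and `occupancy`.
#' @export
simulate_tf_mean_ode <- function(driver_A_TF, tf, times, p0 = 0,
                                 atol = 1e-10, rtol = 1e-9, max_step = 0.05) {
  driver_A_TF <- as_driver(driver_A_TF)
  rhs <- function(t, y, p) {
    A <- driver_value(driver_A_TF, t)
    list(tf$k_a * A * (1 - y[1L]) - tf$k_delta * y[1L])
  }
  sol <- deSolve::ode(y = c(p = p0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol,
                      hmax = max_step)
  p <- as.numeric(sol[, "p"])
  trajectory(times, C_TF = p / tf$V, occupancy = p)
}

# Save/restore the global RNG state so seeded simulators do not perturb the
# caller's random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
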