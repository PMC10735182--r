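#' Parameters of the positive-autoregulation circuit
#'
#' A transcription factor that activates its own transcription after
#' homodimerisation, with the dimer-promoter binding facilitated by an
#' inducer. The circuit skeleton is: monomer production (basal plus
#' occupancy-proportional transcription times translation), monomer-dimer
#' mass action, dimer-promoter binding with the inducer level `eta` scaling
#' the effective binding affinity, first-order mRNA decay, and protein
#' removal at rate `r` (degradation plus dilution).
#'
#' The dimerisation follows the pairwise-binding formalism with
#' \eqn{A(t) = B(t) = P(t)} (total protein), so the free-monomer level is
#' \eqn{P - C}; the promoter is a single DNA site whose occupancy follows the
#' TF-DNA master-equation mean with the dimer concentration as the TF level
#' and association rate \eqn{\eta k_a}.
#'
#' The default rates place the dimer and promoter kinetics in the
#' fast-binding regime (sub-minute relaxation), where the quasi-steady-state
#' reduction looks safest and the near-transition failure of that reduction
#' is therefore most striking.
#'
#' @param alpha0 basal transcription rate (mRNA concentration / h).
#' @param alpha occupancy-activated transcription rate (mRNA concentration / h).
#' @param beta_m mRNA decay rate (1/h).
#' @param kappa translation rate (protein per mRNA per h).
#' @param r protein degradation-plus-dilution rate (1/h).
#' @param dimer [binding_params()] of monomer dimerisation.
#' @param tf [tf_params()] of the dimer-promoter interaction (at inducer
#'   level \eqn{\eta = 1}; `eta` divides the effective `K`).
#' @param u_bar dimensionless parameter of the analytic response-time gap
#'   (enters only its final logarithmic term; default 1, which makes that
#'   term vanish).
#' @return An object of class `autoreg_params`.
#' @export
autoreg_params <- function(alpha0 = 0.005, alpha = 0.25, beta_m = 0.5,
                           kappa = 1, r = 0.1,
                           dimer = binding_params(K = 1, k_delta = 36),
                           tf = tf_params(K = 3.2, k_delta = 36, V = 1),
                           u_bar = 1) {
  stopifnot(alpha0 > 0, alpha > 0, beta_m > 0, kappa > 0, r > 0,
            inherits(dimer, "binding_params"), inherits(tf, "tf_params"))
  structure(list(alpha0 = alpha0, alpha = alpha, beta_m = beta_m,
                 kappa = kappa, r = r, dimer = dimer, tf = tf,
                 u_bar = u_bar),
            class = "autoreg_params")
}

# quasi-steady-state promoter occupancy probability given total protein P
.autoreg_occ <- function(P, params, eta) {
  if (eta <= 0) return(rep_len(0, length(P)))
  C <- complex_tqssa(P, P, params$dimer)
  K_eff <- params$tf$K / eta
  C / (K_eff + C)
}

# production-balance function: roots of f(P) = 0 are steady states of every
# variant (delay terms are inert at fixed points)
.autoreg_balance <- function(P, params, eta) {
  occ <- .autoreg_occ(P, params, eta)
  params$kappa * (params$alpha0 + params$alpha * occ) /
    (params$beta_m * params$r) - P
}

#' Steady states of the autoregulation circuit
#'
#' Enumerates all fixed points at inducer level `eta` by sign changes of the
#' production-removal balance on a fine protein grid, refined with
#' [stats::uniroot()]. Fixed points are shared by the full, QSSA and ETS
#' variants because every delay and relaxation term vanishes at a steady
#' state. Stability follows from the sign of the balance slope.
#'
#' @param params an [autoreg_params()].
#' @param eta inducer-level proxy (>= 0).
#' @return data.frame with columns `P`, `M`, `C`, `occupancy`, `stable`.
#' @export
autoreg_steady_states <- function(params, eta) {
  P_max <- params$kappa * (params$alpha0 + params$alpha) /
    (params$beta_m * params$r)
  grid <- seq(0, P_max * 1.05, length.out = 2000L)
  fv <- .autoreg_balance(grid, params, eta)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (fv[i] == 0) roots <- c(roots, grid[i])
    else if (fv[i] * fv[i + 1L] < 0) {
      roots <- c(roots, stats::uniroot(.autoreg_balance, c(grid[i], grid[i + 1L]),
                                       params = params, eta = eta,
                                       tol = 1e-12)$root)
    }
  }
  roots <- sort(unique(roots))
  h <- max(1e-7, 1e-7 * P_max)
  stable <- vapply(roots, function(p) {
    (.autoreg_balance(p + h, params, eta) -
       .autoreg_balance(p - h, params, eta)) < 0
  }, logical(1))
  occ <- .autoreg_occ(roots, params, eta)
  data.frame(P = roots,
             M = (params$alpha0 + params$alpha * occ) / params$beta_m,
             C = complex_tqssa(roots, roots, params$dimer),
             occupancy = occ, stable = stable)
}

#' Locate the forward tipping point of the bistable circuit
#'
#' Bisects on the disappearance of the low-expression stable branch: below
#' `eta_c` the circuit has two stable states, above it only the induced
#' state survives (a saddle-node bifurcation).
#'
#' @param params an [autoreg_params()].
#' @param eta_range search interval; widened automatically if needed.
#' @param tol relative bisection tolerance on eta.
#' @return list with `eta_c`, the saddle-node protein level `P_sn`, and the
#'   backward tipping point `eta_c_backward` (low edge of the bistable
#'   window), or an error if no bistable window exists in `eta_range`.
#' @export
autoreg_find_eta_c <- function(params, eta_range = c(1e-3, 50), tol = 1e-4) {
  n_stable <- function(eta) sum(autoreg_steady_states(params, eta)$stable)
  probe <- exp(seq(log(eta_range[1L]), log(eta_range[2L]), length.out = 60L))
  ns <- vapply(probe, n_stable, numeric(1))
  bi <- which(ns >= 2)
  if (!length(bi)) stop("no bistable window found in eta_range (monostable)")
  # forward edge: last bistable probe vs next monostable probe
  i_hi <- max(bi)
  if (i_hi == length(probe)) stop("bistable window extends beyond eta_range")
  lo <- probe[i_hi]; hi <- probe[i_hi + 1L]
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (n_stable(mid) >= 2) lo <- mid else hi <- mid
  }
  eta_c <- (lo + hi) / 2
  # backward edge
  i_lo <- min(bi)
  if (i_lo == 1L) {
    eta_cb <- NA_real_
  } else {
    lo2 <- probe[i_lo - 1L]; hi2 <- probe[i_lo]
    while ((hi2 - lo2) / hi2 > tol) {
      mid <- (lo2 + hi2) / 2
      if (n_stable(mid) >= 2) hi2 <- mid else lo2 <- mid
    }
    eta_cb <- (lo2 + hi2) / 2
  }
  ss <- autoreg_steady_states(params, lo)  # just inside the bistable window
  P_sn <- mean(ss$P[1:2])                  # merging low-stable/saddle pair
  list(eta_c = eta_c, P_sn = P_sn, eta_c_backward = eta_cb)
}

#' Bifurcation scan with hysteresis
#'
#' Sweeps the inducer level across `eta_grid` in the given direction,
#' continuing the occupied branch by starting each steady-state search from
#' the previously converged state (nearest-root continuation). Returns the
#' realised branch and the tipping points.
#'
#' @param params an [autoreg_params()].
#' @param eta_grid increasing vector of inducer levels spanning the window.
#' @param direction `"up"` (start on the low branch) or `"down"` (start on
#'   the induced branch).
#' @return An object of class `autoreg_bifurcation`: data.frame
#'   (`eta`, `P`) plus attributes `eta_c`, `eta_c_backward` (NA when the
#'   sweep never leaves its branch, i.e. the scan looks monostable).
#' @export
scan_bifurcation <- function(params, eta_grid, direction = c("up", "down")) {
  direction <- match.arg(direction)
  eta_grid <- sort(eta_grid)
  if (direction == "down") eta_grid <- rev(eta_grid)
  P_prev <- NULL
  P_branch <- numeric(length(eta_grid))
  for (i in seq_along(eta_grid)) {
    ss <- autoreg_steady_states(params, eta_grid[i])
    stab <- ss$P[ss$stable]
    if (!length(stab)) stop("no stable steady state at eta = ", eta_grid[i])
    if (is.null(P_prev)) {
      P_branch[i] <- if (direction == "up") min(stab) else max(stab)
    } else {
      P_branch[i] <- stab[which.min(abs(stab - P_prev))]
    }
    P_prev <- P_branch[i]
  }
  jump <- which(abs(diff(P_branch)) > 5 * pmax(abs(P_branch[-length(P_branch)]),
                                               1e-12))
  eta_c <- if (length(jump)) eta_grid[min(jump)] else NA_real_
  out <- data.frame(eta = eta_grid, P = P_branch)
  structure(out, class = c("autoreg_bifurcation", "data.frame"),
            direction = direction, eta_c = eta_c)
}

#' Simulate one variant of the autoregulation circuit
#'
#' The `full` variant integrates the mass-action ODEs for mRNA, total
#' protein, dimer complex and promoter occupancy. The `qssa` variant
#' replaces dimer and occupancy with their quasi-steady-state laws
#' ([complex_tqssa()] and the TF-DNA QSSA), leaving mRNA and protein ODEs.
#' The `ets` variant replaces them with the delay-corrected laws
#' ([complex_ets()] / [occupancy_ets_tf()]), giving a state-dependent delay
#' differential equation solved by [solve_dde()].
#'
#' @param params an [autoreg_params()].
#' @param variant `"full"`, `"qssa"` or `"ets"`.
#' @param eta inducer level during the simulation.
#' @param y0 named initial state: `M`, `P` (all variants) plus `C`, `p` for
#'   the full variant. Defaults to the uninduced (`eta = 0`) steady state.
#' @param times output grid (h).
#' @param ... solver controls passed on.
#' @return An `ets_trajectory`; all variants report series `M` and `P`.
#' @export
simulate_autoreg <- function(params, variant = c("full", "qssa", "ets"),
                             eta, times, y0 = NULL, ...) {
  variant <- match.arg(variant)
  if (is.null(y0)) y0 <- autoreg_initial_state(params, eta0 = 0)
  ka_d <- params$dimer$k_a; kd_d <- params$dimer$k_delta
  ka_tf <- params$tf$k_a; kd_tf <- params$tf$k_delta
  K_eff <- if (eta > 0) params$tf$K / eta else Inf

  if (variant == "full") {
    rhs <- function(t, y, p) {
      M <- y[1L]; P <- y[2L]; C <- y[3L]; pr <- y[4L]
      dM <- params$alpha0 + params$alpha * pr - params$beta_m * M
      dP <- params$kappa * M - params$r * P
      dC <- ka_d * (P - C)^2 - kd_d * C
      dpr <- eta * ka_tf * C * (1 - pr) - kd_tf * pr
      list(c(dM, dP, dC, dpr))
    }
    sol <- deSolve::ode(y = y0[c("M", "P", "C", "p")], times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        atol = 1e-10, rtol = 1e-8, hmax = 0.05, ...)
    return(trajectory(times, M = as.numeric(sol[, "M"]),
                      P = as.numeric(sol[, "P"]),
                      C = as.numeric(sol[, "C"]),
                      p = as.numeric(sol[, "p"])))
  }

  occ_of_C <- function(C) {
    if (eta <= 0) 0 else C / (K_eff + C)
  }

  if (variant == "qssa") {
    rhs <- function(t, y, p) {
      M <- y[1L]; P <- y[2L]
      C <- complex_tqssa(P, P, params$dimer)
      dM <- params$alpha0 + params$alpha * occ_of_C(C) - params$beta_m * M
      dP <- params$kappa * M - params$r * P
      list(c(dM, dP))
    }
    sol <- deSolve::ode(y = y0[c("M", "P")], times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        atol = 1e-10, rtol = 1e-8, hmax = 0.05, ...)
    return(trajectory(times, M = as.numeric(sol[, "M"]),
                      P = as.numeric(sol[, "P"])))
  }

  # ets: DDE in (M, P); dimer and occupancy laws read delayed protein levels
  C_gamma <- function(t, P_now, hist) {
    tau_d <- effective_delay_pp(P_now, P_now, params$dimer)
    P_lag <- hist(t - tau_d, nr = 2L)
    min(complex_tqssa(P_lag, P_lag, params$dimer), P_now)
  }
  rhs <- function(t, y, hist, p) {
    M <- y[1L]; P <- y[2L]
    Cg <- C_gamma(t, P, hist)
    if (eta <= 0) {
      occ <- 0
    } else {
      tau_tf <- (1 / kd_tf) * K_eff / (K_eff + Cg)
      s <- t - tau_tf
      Cg_lag <- C_gamma(s, hist(s, nr = 2L), hist)
      occ <- Cg_lag / (K_eff + Cg_lag)
    }
    dM <- params$alpha0 + params$alpha * occ - params$beta_m * M
    dP <- params$kappa * M - params$r * P
    list(c(dM, dP))
  }
  solve_dde(rhs, y0 = y0[c("M", "P")], times = times,
            initial_history = function(s) y0[c("M", "P")],
            atol = 1e-10, rtol = 1e-8, max_step = 0.05, ...)
}

#' Uninduced initial state of the circuit
#'
#' The steady state at inducer level `eta0` (lowest stable branch), used as
#' the pre-induction history in all acute-induction experiments.
#'
#' @param params an [autoreg_params()].
#' @param eta0 pre-induction inducer level (default 0).
#' @return named vector `M`, `P`, `C`, `p`.
#' @export
autoreg_initial_state <- function(params, eta0 = 0) {
  ss <- autoreg_steady_states(params, eta0)
  low <- which(ss$stable)[1L]
  c(M = ss$M[low], P = ss$P[low], C = ss$C[low], p = ss$occupancy[low])
}

#' Response time of an induction trajectory
#'
#' Time for the protein level to first reach 90% of its post-induction
#' steady state, located by linear interpolation between grid points.
#' Trajectories already above the threshold at the start return 0;
#' trajectories that never cross raise an error reporting the maximum
#' fraction attained.
#'
#' @param traj an `ets_trajectory` containing series `P` (or the series
#'   named by `series`).
#' @param target_steady the post-induction steady-state protein level.
#' @param series series name (default "P").
#' @param fraction threshold fraction of the steady state (default 0.9).
#' @return time in hours.
#' @export
response_time <- function(traj, target_steady, series = "P", fraction = 0.9) {
  y <- traj$series[[series]]
  if (is.null(y)) stop("trajectory has no series '", series, "'")
  thr <- fraction * target_steady
  if (y[1L] >= thr) return(0)
  above <- which(y >= thr)
  if (!length(above)) {
    stop(sprintf("level never reaches %.0f%% of target (max fraction %.3f)",
                 100 * fraction, max(y) / target_steady))
  }
  i <- above[1L]
  t0 <- traj$times[i - 1L]; t1 <- traj$times[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

# simulate a variant from the uninduced state until the protein crosses
# `fraction` of P_target, extending the horizon as needed
.simulate_to_crossing <- function(params, variant, eta, y0, P_target,
                                  fraction = 0.9, t_max0 = 100,
                                  t_cap = 20000, dt = 0.05) {
  t_max <- t_max0
  repeat {
    times <- seq(0, t_max, by = dt)
    tr <- simulate_autoreg(params, variant, eta, times, y0 = y0)
    if (max(tr$series$P) >= fraction * P_target) return(tr)
    if (t_max >= t_cap) {
      stop("no crossing by t = ", t_max, " h (max fraction ",
           round(max(tr$series$P) / P_target, 3), ")")
    }
    t_max <- min(t_max * 3, t_cap)
  }
}

#' Acute-induction experiment across model variants
#'
#' Starts every variant from the shared uninduced steady state, switches the
#' inducer to `eta_post` at time 0, and reports the 90% response time of
#' each variant together with the pairwise gaps relative to the full model.
#' The quasi-steady-state reduction systematically shortens the response
#' time (it discards the effective delays in dimerisation and promoter
#' binding); the delay-corrected reduction tracks the full model closely.
#'
#' @param params an [autoreg_params()].
#' @param eta_post inducer level after induction; must exceed the tipping
#'   point.
#' @param variants subset of `c("full", "qssa", "ets")`.
#' @param dt output step (h).
#' @return list with `response_times` (named vector), `gaps` (full minus
#'   each reduced variant), `P_target`, and the trajectories.
#' @export
induction_experiment <- function(params, eta_post,
                                 variants = c("full", "qssa", "ets"),
                                 dt = 0.05) {
  ss_post <- autoreg_steady_states(params, eta_post)
  stab <- ss_post[ss_post$stable, ]
  P_target <- max(stab$P)
  y0 <- autoreg_initial_state(params, eta0 = 0)
  if (y0["P"] >= 0.9 * P_target) {
    stop("eta_post does not induce a distinct high state")
  }
  trajs <- list(); rts <- c()
  for (v in variants) {
    tr <- .simulate_to_crossing(params, v, eta_post, y0, P_target, dt = dt)
    trajs[[v]] <- tr
    rts[v] <- response_time(tr, P_target)
  }
  gaps <- c()
  if ("full" %in% variants) {
    for (v in setdiff(variants, "full")) {
      gaps[paste0("full_minus_", v)] <- rts[["full"]] - rts[[v]]
    }
  }
  list(response_times = rts, gaps = gaps, P_target = P_target,
       trajectories = trajs)
}

#' Analytic response-time gap between the exact and QSSA descriptions
#'
#' Leading-order analytic estimate of how much longer the exact response
#' time is than its quasi-steady-state-based estimate after acute induction
#' to inducer level `eta` above the tipping point `eta_c`:
#' \deqn{\frac{2\pi}{r}\sqrt{\frac{\eta_c}{\eta-\eta_c}}
#'   \left(\frac{1}{D}+\frac{1}{D_{TF}}\right)
#'   + \frac{1}{r}\ln\!\left(1+\frac{1}{D}+\frac{1}{D_{TF}}\right)
#'   + \frac{1}{r}\left(\frac{1}{D}+\frac{1}{D_{TF}}\right)
#'   \ln\!\left\{1+\frac{D D_{TF}(\bar u - 1)\,[D D_{TF}(\bar u -1)
#'   - 2(D+D_{TF})]}{(D+D_{TF})^2}\right\}.}
#' `D` and `D_TF` are the reciprocals of the effective time delays of the
#' dimerisation and dimer-promoter steps at the transition bottleneck
#' (see [autoreg_delay_rates()]). The gap diverges as
#' \eqn{1/\sqrt{(\eta-\eta_c)/\eta_c}} when the inducer approaches the
#' tipping point (critical slowing down amplifies the delays), tends to the
#' finite sum of the logarithmic terms far from it, and vanishes as the
#' total delay \eqn{D^{-1}+D_{TF}^{-1} \to 0}.
#'
#' @param eta inducer level (> eta_c).
#' @param eta_c tipping point.
#' @param r protein removal rate (1/h).
#' @param D,D_TF reciprocal effective delays (1/h).
#' @param u_bar dimensionless shape parameter of the final log term
#'   (default 1: term vanishes).
#' @return gap in hours.
#' @export
response_time_gap_analytic <- function(eta, eta_c, r, D, D_TF, u_bar = 1) {
  stopifnot(r > 0, D > 0, D_TF > 0)
  if (any(eta <= eta_c)) stop("eta must exceed eta_c")
  S <- 1 / D + 1 / D_TF
  term1 <- (2 * pi / r) * sqrt(eta_c / (eta - eta_c)) * S
  term2 <- log(1 + S) / r
  q <- D * D_TF * (u_bar - 1)
  arg <- 1 + q * (q - 2 * (D + D_TF)) / (D + D_TF)^2
  if (arg <= 0) stop("logarithm argument non-positive; check u_bar")
  term3 <- (S / r) * log(arg)
  term1 + term2 + term3
}

#' Dimensionless reciprocal delays at the transition bottleneck
#'
#' The analytic response-time gap is written in terms of `D` and `D_TF`,
#' dimensionless parameters inversely proportional to the effective time
#' delays of the dimerisation and promoter-binding steps: here
#' \eqn{D = [r\,\tau_{dim}]^{-1}} and \eqn{D_{TF} = [r\,\tau_{TF}]^{-1}},
#' the delays measured in units of the protein lifetime \eqn{1/r}. Both
#' delays are evaluated at the saddle-node protein level, the bottleneck
#' state where the induced trajectory lingers and the delay amplification
#' happens: \eqn{\tau_{dim} = [k_\delta \Delta_{tQ}(P_{sn})]^{-1}} and
#' \eqn{\tau_{TF} = k_\delta^{-1} K_{eff}/(K_{eff} + C_{sn})} with
#' \eqn{K_{eff} = K/\eta_c} and \eqn{C_{sn}} the dimer level at the
#' bottleneck. With this normalisation \eqn{(D^{-1}+D_{TF}^{-1})/r} is the
#' total bottleneck delay \eqn{\tau_{dim} + \tau_{TF}} in hours.
#'
#' @param params an [autoreg_params()].
#' @param eta_c,P_sn tipping point and saddle-node protein level; computed
#'   by [autoreg_find_eta_c()] when omitted.
#' @return list with `D`, `D_TF`, `S = 1/D + 1/D_TF` (dimensionless),
#'   `tau_total` (h), `eta_c`, `P_sn`.
#' @export
autoreg_delay_rates <- function(params, eta_c = NULL, P_sn = NULL) {
  if (is.null(eta_c) || is.null(P_sn)) {
    cc <- autoreg_find_eta_c(params)
    eta_c <- cc$eta_c; P_sn <- cc$P_sn
  }
  tau_dim <- effective_delay_pp(P_sn, P_sn, params$dimer)
  C_sn <- complex_tqssa(P_sn, P_sn, params$dimer)
  K_eff <- params$tf$K / eta_c
  tau_tf <- (1 / params$tf$k_delta) * K_eff / (K_eff + C_sn)
  D <- 1 / (params$r * tau_dim)
  D_TF <- 1 / (params$r * tau_tf)
  list(D = D, D_TF = D_TF, S = 1 / D + 1 / D_TF,
       tau_total = tau_dim + tau_tf, eta_c = eta_c, P_sn = P_sn)
}

#' Scaling of the response-time gap near the tipping point
#'
#' Runs acute-induction experiments at each inducer level in `eta_values`,
#' computes the full-model minus QSSA-model response-time gap, and
#' regresses it against \eqn{1/\sqrt{(\eta-\eta_c)/\eta_c}} by ordinary
#' least squares. The analytic theory predicts a line with slope
#' \eqn{2\pi (D^{-1}+D_{TF}^{-1})/r}; the returned `slope_normalized`
#' divides the fitted slope by \eqn{(D^{-1}+D_{TF}^{-1})/r} so the theory
#' value is \eqn{2\pi \approx 6.28}.
#'
#' With `gaps = "analytic"` the regression is run on the analytic gaps
#' instead of simulations (a closed-form check: slope exactly \eqn{2\pi},
#' \eqn{R^2 = 1}).
#'
#' @param params an [autoreg_params()].
#' @param eta_values >= 3 inducer levels above the tipping point.
#' @param gaps `"simulated"` or `"analytic"`.
#' @param dt simulation output step (h).
#' @return list with `slope`, `slope_normalized`, `r_squared`, `eta_c`,
#'   `S_over_r`, and the per-eta table `data`.
#' @export
slope_scaling_experiment <- function(params, eta_values,
                                     gaps = c("simulated", "analytic"),
                                     dt = 0.05) {
  gaps <- match.arg(gaps)
  if (length(eta_values) < 3L) stop("need at least 3 eta values")
  rates <- autoreg_delay_rates(params)
  eta_c <- rates$eta_c
  if (any(eta_values <= eta_c)) stop("all eta values must exceed eta_c")
  x <- 1 / sqrt((eta_values - eta_c) / eta_c)
  g <- if (gaps == "analytic") {
    vapply(eta_values, function(e)
      response_time_gap_analytic(e, eta_c, params$r, rates$D, rates$D_TF,
                                 params$u_bar), numeric(1))
  } else {
    vapply(eta_values, function(e) {
      ex <- induction_experiment(params, e, variants = c("full", "qssa"),
                                 dt = dt)
      unname(ex$gaps["full_minus_qssa"])
    }, numeric(1))
  }
  fit <- stats::lm(g ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((g - mean(g))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       slope_normalized = unname(stats::coef(fit)[2L]) / (rates$S / params$r),
       r_squared = r2,
       eta_c = eta_c, S_over_r = rates$S / params$r,
       data = data.frame(eta = eta_values, x = x, gap = g))
}

#' Ensemble of response-time-gap scaling experiments
#'
#' Repeats [slope_scaling_experiment()] over random circuit
#' parameterisations: protein removal rate, dimer/promoter kinetic rates
#' and binding constants are drawn log-uniformly over physiological ranges
#' (fast sub-hour binding kinetics, multi-hour protein lifetimes). Draws
#' without a bistable window are discarded and redrawn. Induction levels
#' span one decade of relative distance to each draw's tipping point.
#'
#' @param n_draws number of bistable parameter draws analysed.
#' @param seed RNG seed.
#' @param rel_eta relative distances \eqn{(\eta-\eta_c)/\eta_c} probed.
#' @param r_range,k_delta_range,K_dimer_range,K_tf_range sampling ranges.
#' @param dt simulation output step (h).
#' @return data.frame with one row per draw (`slope_normalized`,
#'   `r_squared`, `eta_c`, parameters).
#' @export
autoreg_slope_ensemble <- function(n_draws, seed,
                                   rel_eta = exp(seq(log(0.05), log(0.5),
                                                     length.out = 8)),
                                   r_range = c(0.08, 0.25),
                                   k_delta_range = c(15, 80),
                                   K_dimer_range = c(0.5, 2),
                                   K_tf_range = c(1.5, 6),
                                   dt = 0.05) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  rlu <- function(rng) exp(stats::runif(1, log(rng[1L]), log(rng[2L])))
  res <- list(); attempts <- 0L
  while (length(res) < n_draws && attempts < 10L * n_draws) {
    attempts <- attempts + 1L
    p <- autoreg_params(r = rlu(r_range),
                        dimer = binding_params(K = rlu(K_dimer_range),
                                               k_delta = rlu(k_delta_range)),
                        tf = tf_params(K = rlu(K_tf_range),
                                       k_delta = rlu(k_delta_range), V = 1))
    sc <- tryCatch({
      cc <- autoreg_find_eta_c(p)
      slope_scaling_experiment(p, cc$eta_c * (1 + rel_eta), dt = dt)
    }, error = function(e) NULL)
    if (is.null(sc)) next
    res[[length(res) + 1L]] <- data.frame(
      draw = length(res) + 1L, slope_normalized = sc$slope_normalized,
      r_squared = sc$r_squared, eta_c = sc$eta_c, r = p$r,
      k_delta_dimer = p$dimer$k_delta, k_delta_tf = p$tf$k_delta,
      K_dimer = p$dimer$K, K_tf = p$tf$K)
  }
  if (length(res) < n_draws) {
    warning("only ", length(res), " bistable draws found")
  }
  do.call(rbind, res)
}
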