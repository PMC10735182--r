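test_that("uninduced steady state is the basal-expression fixed point", {
  p <- autoreg_params()
  ss <- autoreg_steady_states(p, eta = 0)
  expect_equal(nrow(ss), 1L)
  expect_true(ss$stable)
  # eta = 0 kills the feedback: P = kappa alpha0 / (beta_m r)
  expect_equal(ss$P, p$kappa * p$alpha0 / (p$beta_m * p$r), tolerance = 1e-9)
  expect_equal(ss$occupancy, 0)
})

test_that("all variants share fixed points and stay on them", {
  p <- autoreg_params()
  eta <- 3.5
  ss <- autoreg_steady_states(p, eta)
  hi <- ss[ss$stable, ][which.max(ss$P[ss$stable]), ]
  y0 <- c(M = hi$M, P = hi$P, C = hi$C, p = hi$occupancy)
  tt <- seq(0, 20, by = 0.05)
  for (v in c("full", "qssa", "ets")) {
    tr <- simulate_autoreg(p, v, eta, tt, y0 = y0)
    expect_lt(max(abs(tr$series$P - hi$P)) / hi$P, 1e-4)
  }
})

test_that("full model relaxes to the algebraic fixed point", {
  p <- autoreg_params()
  eta <- 5
  ss <- autoreg_steady_states(p, eta)
  P_hi <- max(ss$P[ss$stable])
  y0 <- autoreg_initial_state(p)
  tr <- simulate_autoreg(p, "full", eta, seq(0, 400, by = 0.05), y0 = y0)
  expect_equal(tr$series$P[length(tr$times)], P_hi, tolerance = 1e-4)
})

test_that("bifurcation scan shows hysteresis with a stable tipping point", {
  p <- autoreg_params()
  grid <- seq(0.5, 4, by = 0.05)
  up <- scan_bifurcation(p, grid, "up")
  dn <- scan_bifurcation(p, grid, "down")
  cc <- autoreg_find_eta_c(p)
  # inside the bistable window the up branch stays below the down branch
  win <- up$eta > cc$eta_c_backward + 0.1 & up$eta < cc$eta_c - 0.1
  expect_true(all(up$P[win] < dn$P[match(up$eta[win], dn$eta)]))
  expect_lt(cc$eta_c_backward, cc$eta_c)
  # the scan's jump location brackets the bisected tipping point
  expect_lt(abs(attr(up, "eta_c") - cc$eta_c), 2 * 0.05)
  # bisection is stable under tolerance refinement
  cc2 <- autoreg_find_eta_c(p, tol = 1e-5)
  expect_lt(abs(cc2$eta_c - cc$eta_c) / cc$eta_c, 1e-3)
})

test_that("a weak-feedback circuit is monostable with identical sweeps", {
  p <- autoreg_params(alpha = 0.006)
  grid <- seq(0.5, 4, by = 0.25)
  up <- scan_bifurcation(p, grid, "up")
  dn <- scan_bifurcation(p, grid, "down")
  expect_equal(up$P, dn$P[match(up$eta, dn$eta)], tolerance = 1e-8)
  expect_true(is.na(attr(up, "eta_c")))
  expect_error(autoreg_find_eta_c(p), "monostable|beyond")
})

test_that("response_time interpolates the 90% crossing", {
  r <- 0.25
  tt <- seq(0, 60, by = 0.05)
  tr <- trajectory(tt, P = 3 * (1 - exp(-r * tt)))
  expect_equal(response_time(tr, 3), log(10) / r, tolerance = 1e-3)
  tr_hi <- trajectory(tt, P = rep(5, length(tt)))
  expect_equal(response_time(tr_hi, 3), 0)
  tr_low <- trajectory(tt, P = rep(0.1, length(tt)))
  expect_error(response_time(tr_low, 3), "never reaches")
})

test_that("QSSA underestimates the induction response time; ETS tracks it", {
  p <- autoreg_params()
  ex <- induction_experiment(p, eta_post = 3.0)
  rt <- ex$response_times
  expect_gt(rt[["full"]], rt[["qssa"]])
  expect_lt(abs(rt[["full"]] - rt[["ets"]]),
            abs(rt[["full"]] - rt[["qssa"]]))
})

test_that("analytic response-time gap has the printed structure", {
  # vanishes with the total delay
  expect_equal(response_time_gap_analytic(3, 2, r = 0.1, D = 1e9, D_TF = 1e9),
               0, tolerance = 1e-6)
  # diverges towards the tipping point
  g_near <- response_time_gap_analytic(2.001, 2, 0.1, 20, 30)
  g_far <- response_time_gap_analytic(20, 2, 0.1, 20, 30)
  expect_gt(g_near, 10 * g_far)
  # first two terms symmetric under D <-> D_TF (u_bar = 1 kills the third)
  expect_equal(response_time_gap_analytic(3, 2, 0.1, 20, 30),
               response_time_gap_analytic(3, 2, 0.1, 30, 20))
  expect_error(response_time_gap_analytic(1.9, 2, 0.1, 20, 30), "exceed")
  # slope of gap vs 1/sqrt((eta-eta_c)/eta_c) is exactly 2 pi (1/D+1/D_TF)/r
  eta_c <- 2; r <- 0.1; D <- 25; D_TF <- 40
  etas <- eta_c * (1 + c(0.05, 0.1, 0.2, 0.4, 0.8))
  gap <- response_time_gap_analytic(etas, eta_c, r, D, D_TF)
  x <- 1 / sqrt((etas - eta_c) / eta_c)
  slope <- coef(lm(gap ~ x))[[2L]]
  expect_equal(slope, 2 * pi * (1 / D + 1 / D_TF) / r, tolerance = 1e-9)
})

test_that("slope experiment on analytic gaps recovers 2 pi exactly", {
  p <- autoreg_params()
  cc <- autoreg_find_eta_c(p)
  sc <- slope_scaling_experiment(p, cc$eta_c * (1 + c(0.05, 0.1, 0.2, 0.4)),
                                 gaps = "analytic")
  expect_equal(sc$slope_normalized, 2 * pi, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-9)
  expect_error(slope_scaling_experiment(p, cc$eta_c * c(1.1, 1.2)),
               "at least 3")
})
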