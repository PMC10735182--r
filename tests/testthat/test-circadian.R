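test_that("constant production drives every species to g/a_i", {
  a <- c(0.4, 0.9, 1.5)
  casc <- ptm_cascade(a, driver_constant(2))
  tt <- seq(0, 200, by = 0.1)
  tr <- simulate_cascade(casc, tt, A0 = rep(0, 3))
  final <- vapply(c("A0", "A1", "A2"), function(s)
    tr$series[[s]][length(tt)], numeric(1))
  expect_equal(unname(final), 2 / a, tolerance = 1e-6)
})

test_that("without production the total protein only decreases", {
  casc <- ptm_cascade(c(0.5, 1), driver_constant(0))
  tr <- simulate_cascade(casc, seq(0, 30, by = 0.1), A0 = c(2, 1))
  expect_true(all(diff(tr$series$A_total) <= 1e-10))
})

test_that("mass balance holds along the simulated cascade", {
  casc <- default_cascade(2)
  tt <- seq(0, 48, by = 0.05)
  tr <- simulate_cascade(casc, tt)
  tot <- tr$series$A_total
  mid <- seq(2, length(tt) - 1L)
  dtot <- (tot[mid + 1L] - tot[mid - 1L]) / (2 * 0.05)
  flux <- driver_value(casc$g, tt[mid]) -
    casc$a[casc$n + 1L] * tr$series[[paste0("A", casc$n)]][mid]
  expect_lt(max(abs(dtot - flux)), 1e-3)
})

test_that("rhythmic production settles onto a 24-h periodic orbit", {
  casc <- default_cascade(1)
  t_end <- 12 * 24
  tt <- seq(0, t_end, by = 0.05)
  tr <- simulate_cascade(casc, tt)
  i_last <- which(tt >= t_end - 24)
  expect_lt(max(abs(tr$series$A_total[i_last] -
                      tr$series$A_total[i_last - 480L])) /
              mean(tr$series$A_total[i_last]), 1e-6)
})

test_that("steady-state degradation rate is the harmonic combination", {
  # single PTM: a0 a1 / (a0 + a1)
  a <- c(0.4, 0.9)
  casc <- ptm_cascade(a, driver_constant(1.3))
  tt <- seq(0, 300, by = 0.1)
  tr <- simulate_cascade(casc, tt)
  keep <- tt > 250
  cyc <- trajectory(tt[keep], lapply(tr$series, function(s) s[keep]))
  rate <- degradation_rate(cyc, a[2L])$series$rate
  expect_equal(mean(rate), prod(a) / sum(a), tolerance = 1e-6)
  # general n: (sum_i 1/a_i)^{-1}
  a3 <- c(0.3, 0.8, 1.1, 2.0)
  tr3 <- simulate_cascade(ptm_cascade(a3, driver_constant(1)), tt)
  cyc3 <- trajectory(tt[keep], lapply(tr3$series, function(s) s[keep]))
  rate3 <- degradation_rate(cyc3, a3[4L])$series$rate
  expect_equal(mean(rate3), 1 / sum(1 / a3), tolerance = 1e-6)
})

test_that("slowest_two orders by magnitude with pathway-order tie-break", {
  expect_equal(slowest_two(c(5, 1, 3))[c("a_u", "a_v")], list(a_u = 1, a_v = 3))
  expect_equal(slowest_two(c(5, 1, 3))[c("u", "v")], list(u = 1L, v = 2L))
  expect_equal(slowest_two(c(2, 2, 7))[c("u", "v")], list(u = 0L, v = 1L))
  st <- slowest_two(default_cascade(1, a = c(0.3, 0.7)))
  expect_equal(st$a_u, 0.3); expect_equal(st$a_v, 0.7)
})

test_that("delay-corrected rate is constant for constant protein", {
  a_u <- 0.4; a_v <- 0.9
  d <- driver_constant(2)
  est <- degradation_rate_ets(d, a_u, a_v, times = seq(0, 24, by = 0.1))
  expect_equal(est$series$rate, rep(a_u * a_v / (a_u + a_v), 241),
               tolerance = 1e-12)
})

test_that("delay-corrected rate matches its first-order expansion when slow", {
  a_u <- 0.5; a_v <- 1.2
  base <- a_u * a_v / (a_u + a_v)
  d <- driver_sinusoid(10, 0.1, period = 240)  # slow, shallow rhythm
  tt <- seq(240, 480, by = 1)
  est <- degradation_rate_ets(d, a_u, a_v, times = tt)
  h <- 1e-4
  Aprime <- (driver_value(d, tt + h) - driver_value(d, tt - h)) / (2 * h)
  taylor <- base * (1 - (1 / (a_u + a_v)) * Aprime / driver_value(d, tt))
  # residual is second order in the delay: ~ tau^2 A''/(2A)
  Asec <- (driver_value(d, tt + h) - 2 * driver_value(d, tt) +
             driver_value(d, tt - h)) / h^2
  tau <- 1 / (a_u + a_v)
  bound <- tau^2 / 2 * max(abs(Asec / driver_value(d, tt)))
  expect_lt(max(abs(est$series$rate - taylor)) / base, 2 * bound)
})

test_that("simulated and delay-predicted degradation rates peak together", {
  casc <- default_cascade(1, a = c(0.3, 0.7))
  cyc <- cascade_limit_cycle(casc)
  sim <- degradation_rate(cyc, 0.7)
  st <- slowest_two(casc)
  est <- degradation_rate_ets(cyc, st$a_u, st$a_v, periodic = TRUE)
  p_sim <- etslaw:::.peak_time_periodic(sim$times, sim$series$rate)
  p_est <- etslaw:::.peak_time_periodic(est$times, est$series$rate)
  d <- (p_sim - p_est) %% 24
  if (d > 12) d <- d - 24
  expect_lt(abs(d), 1)
  # and both peak near the peak of -A'/A
  expect_lt(abs(peak_time_difference(sim, cyc)), 1)
})

test_that("relative amplitude: constants, sinusoids, and the delay estimate", {
  expect_equal(relative_amplitude(rep(3, 10)), 0)
  tt <- seq(0, 24 - 0.01, by = 0.01)
  expect_equal(relative_amplitude(2 + 0.5 * sin(2 * pi * tt / 24)),
               2 * 0.5 / 2, tolerance = 1e-3)
  # predicted relative amplitude ~ swing of A'/A divided by (a_u + a_v)
  casc <- default_cascade(1, a = c(0.3, 0.7))
  cyc <- cascade_limit_cycle(casc)
  st <- slowest_two(casc)
  est <- degradation_rate_ets(cyc, st$a_u, st$a_v, periodic = TRUE)
  Afun <- trajectory_fun(cyc, "A_total", periodic = TRUE)
  h <- 1e-3
  logd <- (Afun(cyc$times + h) - Afun(cyc$times - h)) / (2 * h) /
    Afun(cyc$times)
  predicted <- (max(logd) - min(logd)) / (st$a_u + st$a_v)
  measured <- relative_amplitude(est$series$rate)
  expect_lt(abs(measured / predicted - 1), 0.5)  # order-of-magnitude law
})

test_that("peak_time_difference recovers a known shift", {
  tt <- seq(0, 24, by = 0.05)
  A <- trajectory(tt, A = 2 + sin(2 * pi * tt / 24))
  Afun <- trajectory_fun(A, "A", periodic = TRUE)
  h <- 1e-3
  ref <- -(Afun(tt + h) - Afun(tt - h)) / (2 * h) / Afun(tt)
  delta <- 2.5
  ref[length(ref)] <- ref[1L]
  reffun <- splinefun(tt, ref, method = "periodic")
  shifted <- trajectory(tt, rate = reffun(tt - delta) + 1)
  expect_equal(peak_time_difference(shifted, A), delta, tolerance = 0.1)
  flat <- trajectory(tt, rate = rep(1, length(tt)))
  expect_error(peak_time_difference(flat, A), "flat")
})

test_that("degradation rhythmicity grows with the number of modifications", {
  df1 <- degradation_ensemble(1, n_draws = 8, seed = 21)
  df2 <- degradation_ensemble(2, n_draws = 8, seed = 21)
  df3 <- degradation_ensemble(3, n_draws = 8, seed = 21)
  m <- c(median(df1$rel_amp_sim), median(df2$rel_amp_sim),
         median(df3$rel_amp_sim))
  expect_true(all(diff(m) >= 0))
  # amplitude ratio simulated/estimated stays O(1), near 1 for single PTM
  expect_lt(abs(median(df1$amp_ratio) - 1), 0.5)
  expect_true(all(df3$amp_ratio > 0.2 & df3$amp_ratio < 5))
})
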