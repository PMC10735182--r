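test_that("binding_params derives the third constant exactly", {
  expect_equal(binding_params(k_a = 10, k_delta = 1)$K, 0.1)
  expect_equal(binding_params(K = 0.5, k_delta = 2)$k_a, 4)
  expect_error(binding_params(k_a = 1), "exactly two")
  expect_error(binding_params(k_a = -1, k_delta = 1))
})

test_that("delta_tq matches its closed form and the discriminant identity", {
  bp <- binding_params(K = 1, k_delta = 1)
  expect_equal(delta_tq(0, 0, bp), 1)
  expect_equal(delta_tq(1, 1, bp), sqrt(5), tolerance = 1e-12)
  # algebraic identity: (K * delta)^2 = (K + A + B)^2 - 4AB, random inputs
  d <- random_instants(200)
  for (i in seq_len(nrow(d))) {
    bp <- binding_params(K = d$K[i], k_delta = 1)
    lhs <- (d$K[i] * delta_tq(d$A[i], d$B[i], bp))^2
    rhs <- (d$K[i] + d$A[i] + d$B[i])^2 - 4 * d$A[i] * d$B[i]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # symmetry and lower bound
  expect_equal(delta_tq(d$A, d$B, binding_params(K = 1, k_delta = 1)),
               delta_tq(d$B, d$A, binding_params(K = 1, k_delta = 1)))
  expect_true(all(delta_tq(d$A, d$B,
                           binding_params(K = 1, k_delta = 1)) >= 1))
  expect_error(delta_tq(-1, 0, bp), "non-negative")
})

test_that("tQSSA complex is the smaller quadratic root, within bounds", {
  bp <- binding_params(K = 1, k_delta = 1)
  expect_equal(complex_tqssa(1, 1, bp), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(complex_tqssa(0, 5, bp), 0)
  # brute-force root oracle on random inputs
  d <- random_instants(200, seed = 7)
  for (i in seq_len(nrow(d))) {
    bp <- binding_params(K = d$K[i], k_delta = d$k_delta[i])
    C <- complex_tqssa(d$A[i], d$B[i], bp)
    expect_lte(C, min(d$A[i], d$B[i]) * (1 + 1e-12))
    expect_gte(C, 0)
    C_or <- ctq_root_oracle(d$A[i], d$B[i], bp)
    expect_equal(C, C_or, tolerance = 1e-9)
    # residual of the defining quadratic, relative to the flux scale
    resid <- bp$k_a * (d$A[i] - C) * (d$B[i] - C) - bp$k_delta * C
    expect_lt(abs(resid) / max(bp$k_delta * C, 1e-300), 1e-10)
  }
})

test_that("titration limit K -> 0 is computed without cancellation", {
  bp <- binding_params(K = 1e-14, k_delta = 1)
  expect_equal(complex_tqssa(2, 3, bp), 2, tolerance = 1e-10)
  expect_equal(complex_tqssa(5, 1.5, bp), 1.5, tolerance = 1e-10)
})

test_that("Pade form reduces correctly and approaches the tQSSA when valid", {
  bp <- binding_params(K = 1, k_delta = 1)
  expect_equal(complex_sqssa_pade(1, 1, bp), 1 / 3)
  expect_equal(complex_sqssa_pade(0, 7, bp), 0)
  # condition B << K + A: Pade agrees with tQSSA to < 1e-5 relative
  tq <- complex_tqssa(1, 1e-6, bp)
  pd <- complex_sqssa_pade(1, 1e-6, bp)
  expect_lt(abs(pd - tq) / tq, 1e-5)
})

test_that("MM law saturates in substrate with half-saturation at K", {
  bp <- binding_params(K = 2, k_delta = 1)
  expect_equal(complex_mm(2, 10, bp), 5)
  expect_equal(complex_mm(0, 10, bp), 0)
  expect_equal(complex_mm(1e9, 10, bp), 10, tolerance = 1e-6)
  s <- seq(0, 50, by = 0.5)
  expect_true(all(diff(complex_mm(s, 3, bp)) > 0))
})

test_that("effective delay is bounded by 1/k_delta and obeys the identity", {
  bp <- binding_params(K = 1, k_delta = 2)
  expect_equal(effective_delay_pp(0, 0, bp), 0.5)
  expect_equal(effective_delay_pp(1, 1, bp), 1 / (2 * sqrt(5)),
               tolerance = 1e-12)
  d <- random_instants(200, seed = 11)
  for (i in seq_len(nrow(d))) {
    bp <- binding_params(K = d$K[i], k_delta = d$k_delta[i])
    tau <- effective_delay_pp(d$A[i], d$B[i], bp)
    expect_gt(tau, 0)
    expect_lte(tau, 1 / bp$k_delta)
    # printed free-molecule identity
    C <- complex_tqssa(d$A[i], d$B[i], bp)
    tau_id <- (1 / bp$k_delta) /
      (1 + (d$A[i] + d$B[i] - 2 * C) / bp$K)
    expect_equal(tau, tau_id, tolerance = 1e-12)
  }
  # monotone non-increasing in A + B at fixed |A - B| and K
  bp <- binding_params(K = 0.7, k_delta = 1)
  s <- seq(0.5, 20, by = 0.5)
  taus <- effective_delay_pp((s + 0.3) / 2, (s - 0.3) / 2, bp)
  expect_true(all(diff(taus) < 0))
})

test_that("ETS equals the tQSSA for constant drivers and in the fast limit", {
  bp <- binding_params(K = 1, k_delta = 1)
  expect_equal(complex_ets(driver_constant(1), driver_constant(1), 5, bp),
               (3 - sqrt(5)) / 2, tolerance = 1e-12)
  dA <- driver_sinusoid(1, 0.5, 24)
  dB <- driver_constant(0.8)
  tt <- seq(30, 50, by = 0.5)
  fast <- binding_params(K = 1, k_delta = 1e7)
  expect_equal(complex_ets(dA, dB, tt, fast),
               complex_tqssa(driver_value(dA, tt), driver_value(dB, tt),
                             binding_params(K = 1, k_delta = 1e7)),
               tolerance = 1e-6)
})

test_that("ETS beats the tQSSA against the exact dynamics of an oscillation", {
  bp <- binding_params(K = 1, k_delta = 0.5)
  dA <- driver_sinusoid(1, 0.5, period = 24)
  dB <- driver_constant(1)
  tt <- seq(0, 96, by = 0.05)
  ex <- simulate_binding_ode(dA, dB, bp,
                             C0 = complex_tqssa(1, 1, bp), times = tt)
  keep <- tt >= 24  # discard the initial transient
  Cex <- ex$series$C[keep]
  tq <- complex_tqssa(driver_value(dA, tt[keep]), driver_value(dB, tt[keep]),
                      bp)
  ets <- complex_ets(dA, dB, tt[keep], bp)
  expect_lt(rmse(ets, Cex), rmse(tq, Cex))
})

test_that("TF occupancy laws: half-occupancy, bounds, stationary oracle", {
  tf <- tf_params(K = 3, k_delta = 1, V = 2)
  expect_equal(occupancy_qssa_tf(3, tf), 1 / (2 * 2))
  expect_equal(occupancy_qssa_tf(0, tf), 0)
  a <- seq(0, 100, by = 1)
  occ <- tf$V * occupancy_qssa_tf(a, tf)
  expect_true(all(occ >= 0 & occ <= 1))
  expect_true(all(diff(occ) > 0))
  # stationary two-state chain: on-rate k_a A, off-rate k_delta
  # => P(bound) = k_a A / (k_a A + k_delta) = A / (K + A)
  A <- 1.7
  p_stat <- tf$k_a * A / (tf$k_a * A + tf$k_delta)
  expect_equal(p_stat, tf$V * occupancy_qssa_tf(A, tf), tolerance = 1e-14)
})

test_that("TF ETS reduces to QSSA when constant; delay is K/(K+A)/k_delta", {
  tf <- tf_params(K = 1, k_delta = 2, V = 1)
  expect_equal(occupancy_ets_tf(driver_constant(0.6), 10, tf),
               occupancy_qssa_tf(0.6, tf), tolerance = 1e-14)
  expect_equal(effective_delay_tf(1, tf), 1 / (2 * 2))
  expect_true(all(effective_delay_tf(c(0, 1, 10), tf) <= 1 / tf$k_delta))
})

test_that("Levine-Hwa form reduces to the TF QSSA at B = 1/V and to Pade", {
  bp <- binding_params(K = 1, k_delta = 1)
  expect_equal(levine_hwa_mm(1, 1, bp, V = 2), 0.4)
  # B = 1/V: A / (V (K + A))
  V <- 3; A <- 2.5
  expect_equal(levine_hwa_mm(A, 1 / V, bp, V),
               occupancy_qssa_tf(A, tf_params(K = 1, k_delta = 1, V = V)),
               tolerance = 1e-14)
  expect_equal(levine_hwa_mm(2, 3, bp, V = 1e12),
               complex_sqssa_pade(2, 3, bp), tolerance = 1e-10)
  expect_error(levine_hwa_mm(0.01, 0.01, binding_params(K = 1e-3, k_delta = 1),
                             V = 0.5), "denominator")
})
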