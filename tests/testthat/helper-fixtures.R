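# shared fixtures: random kinetic draws and small error helpers

rmse <- function(a, b) sqrt(mean((a - b)^2))

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# log-uniform scalar draw
rlogunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

# random (A, B, K) instants for rate-law identity checks
random_instants <- function(n, seed = 101) {
  set.seed(seed)
  data.frame(A = exp(runif(n, log(1e-3), log(1e2))),
             B = exp(runif(n, log(1e-3), log(1e2))),
             K = exp(runif(n, log(1e-3), log(1e2))),
             k_delta = exp(runif(n, log(1e-2), log(1e2))))
}

# random rhythmic driver with relative amplitude in [0.3, 0.9]
random_sinusoid <- function(period = 24) {
  b <- rlogunif(0.1, 10)
  driver_sinusoid(b, runif(1, 0.3, 0.9) * b, period = period,
                  phase = runif(1, 0, period))
}

# brute-force oracle for the tQSSA: smaller root of
# k_a (A - C)(B - C) = k_delta C found by bisection on [0, min(A,B)]
ctq_root_oracle <- function(A, B, params) {
  f <- function(C) params$k_a * (A - C) * (B - C) - params$k_delta * C
  if (min(A, B) == 0) return(0)
  uniroot(f, c(0, min(A, B)), tol = 1e-15)$root
}

# small cascade used across circadian tests
default_cascade <- function(n = 1, a = NULL, rel_amp = 0.8) {
  if (is.null(a)) a <- seq(0.3, 0.7, length.out = n + 1)
  ptm_cascade(a, driver_sinusoid(1, rel_amp, period = 24))
}

# simulate a cascade to its limit cycle and return the final 24 h cycle
cascade_limit_cycle <- function(cascade, n_transient = 10, period = 24,
                                dt = 0.05) {
  t_end <- (n_transient + 1) * period
  tt <- seq(0, t_end, by = dt)
  traj <- simulate_cascade(cascade, tt)
  keep <- tt >= t_end - period
  trajectory(tt[keep] - (t_end - period),
             lapply(traj$series, function(s) s[keep]))
}
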