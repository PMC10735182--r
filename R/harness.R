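#' Sinusoidal driver (harness alias)
#'
#' Convenience constructor matching the experiment-config vocabulary;
#' identical to [driver_sinusoid()].
#'
#' @inheritParams driver_sinusoid
#' @export
make_sinusoid <- function(baseline, amplitude, period = 24, phase = 0) {
  driver_sinusoid(baseline, amplitude, period, phase)
}

driver_from_spec <- function(spec) {
  kind <- spec$kind %||% "sinusoid"
  switch(kind,
    sinusoid = driver_sinusoid(spec$baseline, spec$amplitude,
                               spec$period %||% 24, spec$phase %||% 0),
    constant = driver_constant(spec$value),
    series = driver_series(spec$times, spec$values,
                           periodic = isTRUE(spec$periodic)),
    csv = {
      df <- utils::read.csv(spec$path)
      driver_series(df[[1L]], df[[2L]], periodic = isTRUE(spec$periodic))
    },
    stop("unknown driver kind: ", kind))
}

#' Read an experiment configuration
#'
#' YAML with fields `experiment`, `seed`, `grid` (`from`, `to`, `by`),
#' a parameter block and driver specs; see the package vignette for the
#' per-experiment schema. The configuration round-trips losslessly through
#' the file.
#'
#' @param path YAML file path.
#' @return named list of class `ets_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment)) stop("config must name an 'experiment'")
  structure(cfg, class = c("ets_config", class(cfg)))
}

config_grid <- function(cfg) {
  g <- cfg$grid %||% list(from = 0, to = 72, by = 0.05)
  seq(g$from, g$to, by = g$by)
}

#' Run a named experiment
#'
#' Orchestrates the package's standard experiments from a configuration
#' list (or YAML path), writing tabular results as CSV and a JSON manifest
#' (parameters, seed, package version) next to them. Runs are deterministic
#' given the seed.
#'
#' Experiments:
#' \describe{
#'   \item{`binding_compare`}{exact pair-binding dynamics vs the tQSSA and
#'     ETS approximants on one grid (series `exact`, `tqssa`, `ets`).}
#'   \item{`autoreg_induce`}{acute-induction response times for the chosen
#'     variants at `eta_post`.}
#'   \item{`degrade_sim`}{cascade simulation plus simulated and
#'     delay-estimated degradation rates on the final cycle.}
#'   \item{`estimate`}{parameter-estimation ensemble and summary.}
#' }
#'
#' @param config an `ets_config`, a plain list, or a YAML file path.
#' @param out_dir output directory (created if missing).
#' @return list with `result` (data.frame), `summary` (list), and the file
#'   paths written.
#' @export
run_experiment <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  name <- config$experiment
  seed <- config$seed %||% 1L
  times <- config_grid(config)
  result <- NULL; summary <- list()

  if (name == "binding_compare") {
    p <- config$params
    bp <- binding_params(K = p$K, k_delta = p$k_delta)
    dA <- driver_from_spec(config$driver_A)
    dB <- driver_from_spec(config$driver_B)
    C0 <- complex_tqssa(driver_value(dA, times[1L]),
                        driver_value(dB, times[1L]), bp)
    exact <- simulate_binding_ode(dA, dB, bp, C0 = C0, times = times)
    tq <- complex_tqssa(driver_value(dA, times), driver_value(dB, times), bp)
    ets <- complex_ets(dA, dB, times, bp)
    result <- data.frame(time = times, exact = exact$series$C,
                         tqssa = tq, ets = ets)
    summary <- list(
      rmse_tqssa = sqrt(mean((tq - exact$series$C)^2)),
      rmse_ets = sqrt(mean((ets - exact$series$C)^2)))
  } else if (name == "autoreg_induce") {
    p <- do.call(autoreg_params, config$params %||% list())
    variants <- config$variants %||% c("full", "qssa", "ets")
    ex <- induction_experiment(p, eta_post = config$eta_post,
                               variants = variants)
    result <- data.frame(variant = names(ex$response_times),
                         response_time_h = unname(ex$response_times))
    summary <- c(as.list(ex$gaps), list(P_target = ex$P_target))
  } else if (name == "degrade_sim") {
    p <- config$params
    g <- driver_from_spec(config$production)
    casc <- ptm_cascade(unlist(p$a), g)
    period <- config$period %||% 24
    t_end <- 11 * period
    tt <- seq(0, t_end, by = 0.05)
    traj <- simulate_cascade(casc, tt)
    keep <- tt >= t_end - period
    cycle <- trajectory(tt[keep] - (t_end - period),
                        lapply(traj$series, function(s) s[keep]))
    sim <- degradation_rate(cycle, casc$a[casc$n + 1L])
    st <- slowest_two(casc)
    est <- degradation_rate_ets(cycle, st$a_u, st$a_v, periodic = TRUE)
    result <- data.frame(time = cycle$times, A = cycle$series$A_total,
                         rate = sim$series$rate, rate_ets = est$series$rate)
    summary <- list(
      peak_diff_h = peak_time_difference(sim, cycle, period = period),
      rel_amp_sim = relative_amplitude(sim$series$rate),
      rel_amp_est = relative_amplitude(est$series$rate))
  } else if (name == "estimate") {
    df <- estimation_ensemble(n_draws = config$n_draws %||% 100,
                              seed = seed,
                              interaction = config$interaction %||% "pp")
    result <- df
    summary <- estimation_summary(df)
  } else {
    stop("unknown experiment: ", name)
  }

  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  json_path <- file.path(out_dir, paste0(name, "_manifest.json"))
  utils::write.csv(result, csv_path, row.names = FALSE)
  manifest <- list(experiment = name, seed = seed,
                   package_version = as.character(utils::packageVersion("etslaw")),
                   config = config[setdiff(names(config), "experiment")],
                   summary = summary)
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(result = result, summary = summary, csv = csv_path, json = json_path)
}

#' Paired permutation test for error comparisons
#'
#' One-tailed significance of the mean difference `mean(x) - mean(y)` under
#' random re-pairing: each permutation swaps a random subset of pairs and
#' the p-value is the fraction of null configurations with a difference at
#' least as extreme (small) as observed. Used to test whether one
#' approximant's errors are systematically below another's.
#'
#' @param x,y paired error vectors (same length).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return p-value for the alternative `mean(x) < mean(y)`.
#' @export
paired_permutation_test <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  obs <- mean(x) - mean(y)
  d <- x - y
  hits <- 0L
  for (i in seq_len(n_perm)) {
    sgn <- sample(c(-1, 1), length(d), replace = TRUE)
    if (mean(sgn * d) <= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
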