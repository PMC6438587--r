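## Figure-caption defaults shared by all experiments:
## threshold 0.5, gain 4, Jbar 1, noise correlation a = 3, b = 0.5,
## weak-coupling scale epsilon = 0.05.
default_experiment_params <- function() {
  list(ring = list(J = 1, gain = 4, threshold = 0.5, f0 = 1, tau = 10),
       grid = list(n_points = 200L),
       noise = list(epsilon = 0.05, a = 3, b = 0.5),
       stimulus = list(contrast = 2, bias = 0))
}

experiment_ids <- c("single_ring_wander", "single_ring_variance",
                    "model_a_stats", "model_a_field", "model_b_surround",
                    "bump_diagnostics")

#' Experiment configuration
#'
#' @param experiment one of `"single_ring_wander"`,
#'   `"single_ring_variance"`, `"model_a_stats"`, `"model_a_field"`,
#'   `"model_b_surround"`, `"bump_diagnostics"`.
#' @param overrides named list of parameter overrides, merged (recursively)
#'   into the figure-caption defaults.
#' @param seed integer RNG seed.
#' @param out_dir output directory (created if missing).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, overrides = list(), seed = 1L,
                              out_dir = tempfile("ringwander-")) {
  experiment <- match.arg(experiment, experiment_ids)
  params <- modifyList(default_experiment_params(), overrides)
  structure(list(experiment = experiment, params = params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

config_ring <- function(cfg) {
  r <- cfg$params$ring
  ring_params(r$J, r$gain, r$threshold, r$f0, r$tau)
}
config_noise <- function(cfg) {
  n <- cfg$params$noise
  noise_params(n$epsilon, n$a, n$b)
}

write_config_echo <- function(cfg, extra = list()) {
  echo <- c(list(experiment = cfg$experiment, seed = cfg$seed,
                 params = cfg$params,
                 package_version = as.character(utils::packageVersion("ringwander"))),
            extra)
  path <- file.path(cfg$out_dir, "config_echo.json")
  jsonlite::write_json(echo, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

write_out <- function(df, cfg, name) {
  path <- file.path(cfg$out_dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run a canned experiment
#'
#' Reproduces the package's standard figure-level experiments from a
#' configuration: bump diagnostics, single-ring wandering and variance
#' tuning, coupled-layer (model A) statistics and field simulations, and
#' surround-modulation (model B) center statistics.  Every run writes its
#' CSV outputs plus a `config_echo.json` sufficient to reproduce it
#' byte-for-byte (same config + seed gives identical files).
#'
#' @param config an [experiment_config()].
#' @return invisibly, a list with `files` (paths written) and `results`
#'   (the computed tables).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(config$experiment,
                bump_diagnostics = exp_bump_diagnostics(config),
                single_ring_wander = exp_single_ring_wander(config),
                single_ring_variance = exp_single_ring_variance(config),
                model_a_stats = exp_model_a_stats(config),
                model_a_field = exp_model_a_field(config),
                model_b_surround = exp_model_b_surround(config))
  res$files <- c(res$files, config_echo = write_config_echo(config))
  invisible(res)
}

exp_bump_diagnostics <- function(cfg) {
  rp <- config_ring(cfg)
  sols <- solve_bump(rp, n_points = cfg$params$grid$n_points)
  tab <- do.call(rbind, lapply(sols, function(b) {
    data.frame(amplitude = b$amplitude, lambda_zero = b$lambda_zero,
               lambda_even = b$lambda_even, stability = b$stability,
               residual = b$residual)
  }))
  list(results = list(bumps = tab),
       files = c(bumps = write_out(tab, cfg, "bump_diagnostics.csv")))
}

exp_single_ring_wander <- function(cfg) {
  rp <- config_ring(cfg)
  np <- config_noise(cfg)
  dur <- cfg$params$duration %||% 1000
  runs <- lapply(c(0, cfg$params$stimulus$contrast), function(h) {
    simulate_field(rp, stimulus_params(h, cfg$params$stimulus$bias), np,
                   duration = dur, seed = cfg$seed,
                   n_points = cfg$params$grid$n_points,
                   snapshot_every = dur / 100)
  })
  phase_tab <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(contrast = c(0, cfg$params$stimulus$contrast)[i],
               time = runs[[i]]$times, beta = runs[[i]]$phases[, 1],
               amplitude = runs[[i]]$amplitudes[, 1])
  }))
  snap_tab <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    do.call(rbind, lapply(seq_along(r$snapshot_times), function(k) {
      data.frame(contrast = c(0, cfg$params$stimulus$contrast)[i],
                 time = r$snapshot_times[k], theta = r$grid$angles,
                 u = r$snapshots[, 1, k])
    }))
  }))
  list(results = list(phases = phase_tab, snapshots = snap_tab),
       files = c(phases = write_out(phase_tab, cfg, "wander_phases.csv"),
                 snapshots = write_out(snap_tab, cfg, "wander_snapshots.csv")))
}

exp_single_ring_variance <- function(cfg) {
  rp <- config_ring(cfg)
  np <- config_noise(cfg)
  sols <- solve_bump(rp, n_points = cfg$params$grid$n_points)
  bump <- Filter(function(b) b$is_stable && b$amplitude > 0, sols)[[1]]
  kappas <- cfg$params$kappas %||% c(0, 0.5, 1, 2, 4, 8)
  theta <- seq(-pi, pi, length.out = 181)
  analytic <- do.call(rbind, lapply(kappas, function(k) {
    vm <- von_mises(k)
    data.frame(kappa = k, theta = theta,
               mean = tuning_mean(theta, bump$amplitude, vm) / bump$amplitude,
               variance = tuning_variance(theta, bump$amplitude, vm) /
                 bump$amplitude^2,
               rate_variance = firing_rate_variance(theta, bump$amplitude,
                                                    vm, rp))
  }))
  amp_tab <- data.frame(kappa = seq(0, 8, by = 0.1))
  amp_tab$mean_amplitude <- vapply(amp_tab$kappa, function(k)
    bessel_ratio(1, k), numeric(1))

  files <- c(analytic = write_out(analytic, cfg, "variance_tuning.csv"),
             amplitude = write_out(amp_tab, cfg, "mean_amplitude.csv"))
  results <- list(analytic = analytic, amplitude = amp_tab, bump = bump)

  n_real <- cfg$params$n_realizations %||% 0
  if (n_real > 0) {   # simulation counterpart (optional, heavier)
    dur <- cfg$params$duration %||% 200
    ens <- ensemble_field(rp, stimulus_params(cfg$params$stimulus$contrast),
                          np, n_realizations = n_real, duration = dur,
                          seed = cfg$seed, save_every = 1,
                          snapshot_every = 1, keep_trajectories = TRUE,
                          n_points = cfg$params$grid$n_points)
    emp <- field_tuning_stats(ens$trajectories, rp, burn_in = dur / 4)
    files <- c(files, empirical = write_out(emp, cfg, "variance_empirical.csv"))
    results$empirical <- emp
  }
  list(results = results, files = files)
}

exp_model_a_stats <- function(cfg) {
  rp <- config_ring(cfg)
  sols <- solve_bump(rp, n_points = cfg$params$grid$n_points)
  bump <- Filter(function(b) b$is_stable && b$amplitude > 0, sols)[[1]]
  A <- bump$amplitude
  kappas <- cfg$params$kappas %||% seq(0, 8, by = 0.5)
  chis <- cfg$params$chis %||% c(0, 1, 5)
  sweep <- do.call(rbind, lapply(chis, function(chi) {
    do.call(rbind, lapply(kappas, function(k) {
      mo <- bivariate_moments(bivariate_cosine_model(k, k, chi))
      data.frame(kappa = k, chi = chi,
                 mean_amplitude = mo$c1,
                 var_min = (1 - mo$c1^2 - (mo$c1^2 - mo$cos2_1)) / 2,
                 var_max = (1 - mo$c1^2 + (mo$c1^2 - mo$cos2_1)) / 2)
    }))
  }))
  theta <- seq(-pi, pi, length.out = 181)
  chi_corr <- cfg$params$chi_corr %||% 5
  corr_tab <- do.call(rbind, lapply(cfg$params$kappas_corr %||% c(0.5, 1, 2, 4),
                                    function(k) {
    st <- model_a_tuning_stats(theta, A,
                               bivariate_cosine_model(k, k, chi_corr))
    data.frame(kappa = k, theta = theta, correlation = st$correlation)
  }))
  list(results = list(sweep = sweep, correlation = corr_tab),
       files = c(sweep = write_out(sweep, cfg, "model_a_sweep.csv"),
                 correlation = write_out(corr_tab, cfg,
                                         "model_a_correlation.csv")))
}

exp_model_a_field <- function(cfg) {
  rp <- config_ring(cfg)
  np <- config_noise(cfg)
  dur <- cfg$params$duration %||% 500
  ## paired-layer runs: equal weak stimuli, and the asymmetric-drive variant
  variants <- cfg$params$variants %||% list(
    list(name = "equal_h0.2_K0",   h = c(0.2, 0.2),  K = 0),
    list(name = "equal_h0.2_K2",   h = c(0.2, 0.2),  K = 2),
    list(name = "asym_h2_h0.25_K0",   h = c(2, 0.25), K = 0),
    list(name = "asym_h2_h0.25_K0.1", h = c(2, 0.25), K = 0.1))
  tab <- do.call(rbind, lapply(variants, function(v) {
    run <- simulate_field(list(rp, rp),
                          list(stimulus_params(v$h[1]), stimulus_params(v$h[2])),
                          np, coupling_params("A", 0, v$K),
                          duration = dur, seed = cfg$seed,
                          n_points = cfg$params$grid$n_points)
    data.frame(variant = v$name, time = run$times,
               beta1 = run$phases[, 1], beta2 = run$phases[, 2])
  }))
  list(results = list(phases = tab),
       files = c(phases = write_out(tab, cfg, "model_a_field_phases.csv")))
}

exp_model_b_surround <- function(cfg) {
  rp <- config_ring(cfg)
  red <- build_phase_reduction(rp, stimulus_params(2), config_noise(cfg),
                               coupling_params("B", 0, 1),
                               n_points = cfg$params$grid$n_points)
  kappa <- cfg$params$kappa %||% 1
  chis <- cfg$params$chis %||% c(-1, -0.5, 0, 0.5, 1)
  biases <- cfg$params$surround_bias %||% seq(-pi, pi, length.out = 25)
  tab <- do.call(rbind, lapply(chis, function(chi) {
    st <- model_b_center_stats(biases, kappa, chi, red)
    st$chi <- chi
    st
  }))
  phi_tab <- data.frame(beta = seq(-pi, pi, length.out = 181))
  phi_tab$phi <- red$potential_phi(phi_tab$beta)
  list(results = list(center = tab, phi = phi_tab),
       files = c(center = write_out(tab, cfg, "model_b_center_stats.csv"),
                 phi = write_out(phi_tab, cfg, "model_b_phi.csv")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the phase reduction against simulation
#'
#' Executes a machine-readable suite of reduction-consistency checks at a
#' configurable scale: (i) the reduced-SDE stationary histogram against
#' the analytic von Mises density; (ii) diffusion recovery (variance
#' growth of the unwrapped phase against `2 * epsilon * D`); (iii) the
#' model-A coupling closed form against adjoint-projection quadrature;
#' (iv) stationarity of the deterministic bump.  Tolerances widen as the
#' realization count shrinks (sampling error scales like
#' `1/sqrt(n_realizations)`); the applied tolerance is reported.
#'
#' @param config an [experiment_config()] (any experiment id); honored
#'   overrides: `n_realizations` (default 50), `duration`.
#' @return a data.frame report with one row per property: `property`,
#'   `statistic`, `tolerance`, `pass`; written alongside as JSON.
#' @export
validate_reduction <- function(config = experiment_config("bump_diagnostics")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- config_ring(config)
  np <- config_noise(config)
  n_real <- config$params$n_realizations %||% 50
  scale_factor <- sqrt(200 / n_real)

  red <- build_phase_reduction(rp, stimulus_params(2), np)
  rows <- list()

  ## (i) reduced SDE stationary histogram vs analytic von Mises
  dur <- config$params$duration %||% 600
  ens <- ensemble_phase_sde(red, n_real, duration = dur, dt = 0.005,
                            seed = config$seed, save_every = 1)
  tv <- phase_tv_distance(ens$phases[[1]][ens$times > dur / 3, ],
                          as_von_mises(red))
  tol_tv <- 0.03 * max(1, scale_factor)
  rows$sde_histogram <- data.frame(property = "sde_vs_von_mises_tv",
                                   statistic = tv, tolerance = tol_tv,
                                   pass = tv < tol_tv)

  ## (ii) diffusion recovery from the unwrapped reduced phase at h = 0:
  ## the free phase diffuses with Var = 2 * eps^2 * D * t
  red0 <- build_phase_reduction(rp, stimulus_params(0), np)
  ens0 <- ensemble_phase_sde(red0, n_real, duration = 200, dt = 0.001,
                             seed = config$seed + 1, save_every = 5)
  v <- apply(ens0$unwrapped[[1]], 1, var)
  slope <- coef(lm(v ~ ens0$times))[2]
  target <- 2 * np$epsilon^2 * red0$diffusion
  rel <- abs(slope - target) / target
  tol_d <- 0.2 * max(1, scale_factor)
  rows$diffusion <- data.frame(property = "diffusion_recovery_rel_err",
                               statistic = rel, tolerance = tol_d,
                               pass = rel < tol_d)

  ## (iii) model A closed form vs quadrature
  bump <- red$bump
  cpl <- coupling_params("A", 1, 2)
  K <- coupling_fn_model_a(cpl, bump, bump)
  betas <- seq(-pi, pi, length.out = 9)
  err <- max(abs(K(betas) -
                   coupling_quadrature_model_a(cpl, bump, bump, betas)))
  rows$coupling <- data.frame(property = "model_a_coupling_quadrature_err",
                              statistic = err, tolerance = 1e-8,
                              pass = err < 1e-8)

  ## (iv) deterministic bump stationarity
  run <- simulate_field(rp, stimulus_params(0), np, duration = 20,
                        noise_on = FALSE, snapshot_every = 20)
  drift <- max(abs(run$snapshots[, 1, dim(run$snapshots)[3]] -
                     run$snapshots[, 1, 1]))
  rows$stationary <- data.frame(property = "deterministic_bump_drift",
                                statistic = drift, tolerance = 1e-6,
                                pass = drift < 1e-6)

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  jsonlite::write_json(report, file.path(config$out_dir,
                                         "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config_echo(config, list(n_realizations = n_real))
  report
}
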