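#' Sample one spatially structured noise increment
#'
#' Draws \eqn{\Delta W} on the ring grid with covariance
#' \eqn{(a/\Delta\theta)\delta_{ij}\,dt + b\cos(\theta_i-\theta_j)\,dt}:
#' independent white terms plus two shared standard-normal amplitudes
#' multiplying \eqn{\cos\theta} and \eqn{\sin\theta} (the exact low-rank
#' decomposition of the cosine kernel; every `a = 0` draw has rank at most
#' 2).
#'
#' @param grid a [ring_grid()].
#' @param noise a [noise_params()] object.
#' @param dt time step.
#' @return numeric vector of increments over the grid.
#' @export
sample_noise_increment <- function(grid, noise, dt) {
  if (dt <= 0) stop("'dt' must be > 0")
  a <- noise$white_weight
  b <- noise$cosine_weight
  dW <- numeric(grid$n_points)
  if (a > 0) dW <- dW + sqrt(a * dt / grid$spacing) * rnorm(grid$n_points)
  if (b > 0) {
    z <- rnorm(2)
    dW <- dW + sqrt(b * dt) * (z[1] * cos(grid$angles) + z[2] * sin(grid$angles))
  }
  dW
}

#' Extract the bump phase from a field snapshot
#'
#' First-circular-harmonic estimator
#' \eqn{\hat\beta = -\arg\big(\sum_i u(\theta_i) e^{i\theta_i}\Delta\theta\big)}:
#' exact (to machine precision) for \eqn{u = A\cos(\theta+\beta)}, and
#' unaffected by even/higher-harmonic contamination (orthogonality).
#' Sign convention: \eqn{U(\theta+\beta)} peaks at \eqn{\theta = -\beta}.
#'
#' @param u field values on the grid.
#' @param grid a [ring_grid()] matching `u`.
#' @return the phase in `[-pi, pi)`.  Errors with `"no bump"` when the
#'   first-harmonic amplitude is below `1e-8`.
#' @export
extract_phase <- function(u, grid = ring_grid(length(u))) {
  z <- sum(u * exp(1i * grid$angles)) * grid$spacing
  if (Mod(z) / pi < 1e-8) stop("no bump: first-harmonic amplitude below 1e-8")
  wrap_angle(-Arg(z))
}

field_config_snapshot <- function(rings, stimuli, noise, coupling, epsilon,
                                  duration, dt, seed, init_phase, n_points) {
  list(rings = lapply(rings, unclass), stimuli = lapply(stimuli, unclass),
       noise = unclass(noise), coupling = unclass(coupling),
       epsilon = epsilon, duration = duration, dt = dt, seed = seed,
       init_phase = init_phase, n_points = n_points)
}

#' Simulate the full stochastic neural field
#'
#' Euler-Maruyama integration (in units of the time constant \eqn{\tau})
#' of one or two coupled ring networks:
#' \deqn{du = [-u + J*f(u) + \epsilon K*f(u_{other}) + \epsilon h]\,dt
#'   + \sqrt{2}\,\epsilon\, dW,}
#' with ring convolutions by the trapezoidal rule, the model-B delta
#' kernel applied pointwise, and noise correlation
#' \eqn{C(\theta) = a\delta(\theta) + b\cos\theta}.  The bump phase is
#' extracted by the first-harmonic estimator at every recording time.
#' Trajectories are bitwise-reproducible given `seed`.
#'
#' @param rings one [ring_params()] or a list of two.
#' @param stimuli one [stimulus_params()] or a list of two.
#' @param noise a [noise_params()]; its `epsilon` scales coupling,
#'   stimulus and noise alike.  Set `noise_on = FALSE` for the
#'   deterministic flow.
#' @param coupling a [coupling_params()].
#' @param duration run length in units of tau.
#' @param dt time step in units of tau (must be `<= 0.01`).
#' @param seed integer RNG seed (optional).
#' @param init_phase initial bump phase(s) \eqn{\beta_0}; initial
#'   condition is `A cos(theta + beta0)` with `A` from [solve_bump()].
#' @param n_points ring grid resolution.
#' @param save_every phase-recording interval in units of tau.
#' @param snapshot_every optional snapshot interval in units of tau
#'   (`NULL` for no activity snapshots).
#' @param noise_on logical; `FALSE` integrates the deterministic field.
#' @param bumps optional pre-solved `bump_solution`(s) for the initial
#'   condition.
#' @return an object of class `field_trajectory`: `grid`, `times`,
#'   `phases` (matrix, one column per network), `amplitudes`, optional
#'   `snapshots` (`n_points` x networks x times array) with
#'   `snapshot_times`, the `seed` and a `config` snapshot.
#' @export
simulate_field <- function(rings, stimuli, noise,
                           coupling = coupling_params("none"),
                           duration = 100, dt = 0.001, seed = NULL,
                           init_phase = 0, n_points = 200L,
                           save_every = 0.1, snapshot_every = NULL,
                           noise_on = TRUE, bumps = NULL) {
  if (dt > 0.01) stop("'dt' must be <= 0.01 (in units of tau)")
  ring_list <- if (inherits(rings, "ring_params")) list(rings) else rings
  stim_list <- if (inherits(stimuli, "stimulus_params")) list(stimuli) else stimuli
  m <- length(ring_list)
  if (m > 2L) stop("at most two networks")
  if (length(stim_list) == 1L) stim_list <- rep(stim_list, m)
  if (length(init_phase) == 1L) init_phase <- rep(init_phase, m)

  if (is.null(bumps)) {
    bumps <- lapply(ring_list, function(rp) {
      sols <- solve_bump(rp, n_points = n_points)
      stable <- Filter(function(b) b$amplitude > 0 && b$is_stable, sols)
      if (length(stable) == 0L) stop("no stable bump for initial condition")
      stable[[length(stable)]]
    })
  } else if (inherits(bumps, "bump_solution")) bumps <- list(bumps)

  grid <- ring_grid(n_points)
  u0 <- vapply(seq_len(m), function(j) {
    bumps[[j]]$amplitude * cos(grid$angles + init_phase[j])
  }, numeric(n_points))

  n_steps <- round(duration / dt)
  save_steps <- max(1L, round(save_every / dt))
  snap_steps <- if (is.null(snapshot_every)) 0L else
    max(1L, round(snapshot_every / dt))
  ## the C++ integrator has its own generator; an unset seed is drawn from
  ## R's RNG so that an outer set.seed() still controls everything
  seed_cpp <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed

  res <- field_euler_cpp(
    u0,
    vapply(ring_list, `[[`, numeric(1), "weight_amplitude"),
    vapply(ring_list, `[[`, numeric(1), "gain"),
    vapply(ring_list, `[[`, numeric(1), "threshold"),
    vapply(ring_list, `[[`, numeric(1), "max_rate"),
    vapply(stim_list, `[[`, numeric(1), "contrast"),
    vapply(stim_list, `[[`, numeric(1), "bias"),
    noise$epsilon, noise$white_weight, noise$cosine_weight,
    switch(coupling$model, none = 0L, A = 1L, B = 2L),
    rep(coupling$uniform_component, m), rep(coupling$modulated_amplitude, m),
    dt, n_steps, save_steps, snap_steps, isTRUE(noise_on),
    as.numeric(seed_cpp))

  structure(list(grid = grid, times = res$phase_times,
                 phases = res$phases, amplitudes = res$amps,
                 snapshots = res$snapshots,
                 snapshot_times = res$snap_times,
                 seed = seed,
                 config = field_config_snapshot(ring_list, stim_list, noise,
                                                coupling, noise$epsilon,
                                                duration, dt, seed,
                                                init_phase, n_points)),
            class = "field_trajectory")
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat(sprintf("field_trajectory: %d network(s), %d grid points, t in [0, %g] tau, %d phase samples\n",
              ncol(x$phases), x$grid$n_points, max(x$times), nrow(x$phases)))
  invisible(x)
}

#' Simulate the reduced stochastic phase equations
#'
#' Euler-Maruyama integration on the circle of
#' \deqn{d\beta_j = -\epsilon\Lambda_j\sin(\beta_j+\bar\theta_j)\,dt
#'   - \epsilon K_j(\beta_j-\beta_{other})\,dt
#'   + \epsilon\sqrt{2 D_j\,dt}\,\xi,}
#' with phases wrapped to `[-pi, pi)` and the per-step increments also
#' accumulated without wrapping (for diffusion estimates).  The
#' single-network case is the von Mises process whose stationary density
#' has concentration \eqn{\kappa = \Lambda/(\epsilon D)}; the variance of
#' the unwrapped free phase grows as \eqn{2\epsilon^2 D\, t}.
#'
#' @param reductions one `phase_reduction` or a list of two (sharing a
#'   coupling model).
#' @param duration run length in units of tau.
#' @param dt time step in units of tau.
#' @param seed integer RNG seed (optional).
#' @param beta0 initial phase(s).
#' @param save_every recording interval in units of tau.
#' @param k_table_n resolution of the internal coupling lookup table
#'   (model B).
#' @return an object of class `phase_trajectory` with `times`, `phases`
#'   (wrapped), `unwrapped`, the `seed` and a snapshot of the reduction
#'   coefficients.
#' @export
simulate_phase_sde <- function(reductions, duration = 1000, dt = 0.001,
                               seed = NULL, beta0 = 0, save_every = 0.1,
                               k_table_n = 4096L) {
  red_list <- if (inherits(reductions, "phase_reduction")) list(reductions)
              else reductions
  m <- length(red_list)
  if (m > 2L) stop("at most two networks")
  if (length(beta0) == 1L) beta0 <- rep(beta0, m)
  model <- red_list[[1]]$coupling_model
  cmodel <- if (m == 1L || model == "none") 0L
            else if (model == "A") 1L else 2L

  k_amp <- vapply(red_list, function(r) {
    if (r$coupling_model == "A") r$coupling_fn(pi / 2) else 0
  }, numeric(1))
  k_values <- numeric(0)
  if (cmodel == 2L) {
    xs <- -pi + (seq_len(k_table_n) - 1L) * (2 * pi / k_table_n)
    k_values <- red_list[[1]]$coupling_fn(xs)
  }
  biases <- vapply(red_list, function(r) {
    if (is.null(r$stimulus)) 0 else r$stimulus$bias
  }, numeric(1))

  n_steps <- round(duration / dt)
  save_steps <- max(1L, round(save_every / dt))
  seed_cpp <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed
  res <- phase_sde_cpp(beta0,
                       vapply(red_list, `[[`, numeric(1), "drift_amplitude"),
                       vapply(red_list, `[[`, numeric(1), "diffusion"),
                       biases, red_list[[1]]$epsilon, cmodel, k_amp,
                       k_values, dt, n_steps, save_steps,
                       as.numeric(seed_cpp))
  structure(list(times = res$times, phases = res$wrapped,
                 unwrapped = res$unwrapped, seed = seed,
                 reduction = lapply(red_list, function(r) {
                   list(Lambda = r$drift_amplitude, D = r$diffusion,
                        epsilon = r$epsilon, model = r$coupling_model)
                 })),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("phase_trajectory: %d network(s), t in [0, %g] tau, %d samples\n",
              ncol(x$phases), max(x$times), nrow(x$phases)))
  invisible(x)
}

## Per-trajectory seeds derived from a master seed by a simple counter:
## trajectory k uses master + k (kept well below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(seed + seq_len(n))
}

#' Ensemble of reduced-phase trajectories
#'
#' Runs [simulate_phase_sde()] `n_realizations` times with per-trajectory
#' seeds `seed + k` and returns the recorded (wrapped and unwrapped)
#' phases stacked realization-by-realization.
#'
#' @inheritParams simulate_phase_sde
#' @param n_realizations number of independent trajectories.
#' @param seed master seed.
#' @return list with `times`, `phases` and `unwrapped` (lists of matrices,
#'   one per network, realizations in columns).
#' @export
ensemble_phase_sde <- function(reductions, n_realizations, duration = 1000,
                               dt = 0.001, seed = NULL, beta0 = 0,
                               save_every = 0.1) {
  seeds <- derive_seeds(seed, n_realizations)
  runs <- lapply(seeds, function(s) {
    simulate_phase_sde(reductions, duration, dt, s, beta0, save_every)
  })
  m <- ncol(runs[[1]]$phases)
  list(times = runs[[1]]$times,
       phases = lapply(seq_len(m), function(j) {
         vapply(runs, function(r) r$phases[, j], numeric(nrow(runs[[1]]$phases)))
       }),
       unwrapped = lapply(seq_len(m), function(j) {
         vapply(runs, function(r) r$unwrapped[, j],
                numeric(nrow(runs[[1]]$phases)))
       }))
}

#' Ensemble of full-field trajectories
#'
#' Runs [simulate_field()] `n_realizations` times with per-trajectory
#' seeds `seed + k`; bumps are solved once and reused.
#'
#' @inheritParams simulate_field
#' @param n_realizations number of independent trajectories.
#' @return list with `times`, `phases` (list of per-network matrices,
#'   realizations in columns) and `trajectories` (the individual runs,
#'   kept only if `keep_trajectories = TRUE`).
#' @param keep_trajectories retain the full `field_trajectory` objects
#'   (memory heavy with snapshots).
#' @export
ensemble_field <- function(rings, stimuli, noise,
                           coupling = coupling_params("none"),
                           n_realizations = 10, duration = 100, dt = 0.001,
                           seed = NULL, init_phase = 0, n_points = 200L,
                           save_every = 0.1, snapshot_every = NULL,
                           keep_trajectories = FALSE) {
  ring_list <- if (inherits(rings, "ring_params")) list(rings) else rings
  bumps <- lapply(ring_list, function(rp) {
    sols <- solve_bump(rp, n_points = n_points)
    stable <- Filter(function(b) b$amplitude > 0 && b$is_stable, sols)
    if (length(stable) == 0L) stop("no stable bump for initial condition")
    stable[[length(stable)]]
  })
  seeds <- derive_seeds(seed, n_realizations)
  runs <- lapply(seeds, function(s) {
    simulate_field(rings, stimuli, noise, coupling, duration, dt, s,
                   init_phase, n_points, save_every, snapshot_every,
                   bumps = bumps)
  })
  m <- ncol(runs[[1]]$phases)
  out <- list(times = runs[[1]]$times,
              phases = lapply(seq_len(m), function(j) {
                vapply(runs, function(r) r$phases[, j],
                       numeric(nrow(runs[[1]]$phases)))
              }),
              bumps = bumps)
  if (keep_trajectories) out$trajectories <- runs
  out
}

#' Empirical circular statistics of an ensemble
#'
#' Pools post-burn-in phases across time and realizations and returns the
#' phase histogram on equal bins, the circular mean and resultant length,
#' and the first circular moment.
#'
#' @param phases matrix of phases (rows = times, columns = realizations)
#'   or a bare vector of phase samples.
#' @param times recording times (required for matrix input with
#'   `burn_in > 0`).
#' @param burn_in time before which samples are discarded.
#' @param bins number of histogram bins on `[-pi, pi)`.
#' @return an object of class `ensemble_stats`: `n_realizations`, `n_pooled`,
#'   `histogram` (data.frame `bin_center`, `density`, `prob`),
#'   `resultant`, `circ_mean`, `moment1` (complex).
#' @export
ensemble_stats <- function(phases, times = NULL, burn_in = 0, bins = 36L) {
  if (is.matrix(phases)) {
    n_real <- ncol(phases)
    if (burn_in > 0) {
      if (is.null(times)) stop("'times' required when burn_in > 0")
      phases <- phases[times > burn_in, , drop = FALSE]
    }
    pooled <- as.numeric(phases)
  } else {
    n_real <- 1L
    pooled <- as.numeric(phases)
  }
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) == 0L) stop("empty post-burn-in window")
  probs <- phase_bin_probs(pooled, bins)
  centers <- -pi + (seq_len(bins) - 0.5) * (2 * pi / bins)
  structure(list(n_realizations = n_real, n_pooled = length(pooled),
                 histogram = data.frame(bin_center = centers,
                                        density = probs / (2 * pi / bins),
                                        prob = probs),
                 resultant = circular_resultant(pooled),
                 circ_mean = circular_mean(pooled),
                 moment1 = mean(exp(1i * pooled))),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble_stats: %d realization(s), %d pooled phases, resultant = %.3f, circular mean = %.3f\n",
              x$n_realizations, x$n_pooled, x$resultant, x$circ_mean))
  invisible(x)
}

#' Total-variation distance between pooled phases and an analytic density
#'
#' Histograms the phases on `bins` equal bins and compares with the exact
#' bin masses of the analytic density (von Mises or any pdf function).
#'
#' @param phases vector (or matrix) of pooled phase samples.
#' @param density a [von_mises()] object or a vectorized pdf function on
#'   `[-pi, pi)`.
#' @param bins number of bins.
#' @return the total-variation distance in `[0, 1]`.
#' @export
phase_tv_distance <- function(phases, density, bins = 36L) {
  pooled <- as.numeric(phases)
  pooled <- pooled[is.finite(pooled)]
  pdf_fun <- if (inherits(density, "von_mises")) {
    function(b) von_mises_pdf(b, density)
  } else density
  tv_distance(phase_bin_probs(pooled, bins), density_bin_probs(pdf_fun, bins))
}

#' Per-preference tuning statistics from field snapshots
#'
#' Pools post-burn-in activity snapshots across time and realizations and
#' returns, for each grid angle, the sample mean and variance of the
#' activity `u` and of the firing rate `f(u)`.
#'
#' @param runs list of `field_trajectory` objects simulated with
#'   `snapshot_every` set.
#' @param params a [ring_params()] for the firing rate.
#' @param burn_in time before which snapshots are discarded.
#' @param network which network (1 or 2).
#' @return data.frame with columns `theta`, `mean_u`, `var_u`, `mean_f`,
#'   `var_f`.
#' @export
field_tuning_stats <- function(runs, params, burn_in = 0, network = 1L) {
  mats <- lapply(runs, function(r) {
    if (is.null(r$snapshots)) stop("trajectories carry no snapshots")
    keep <- r$snapshot_times > burn_in
    if (!any(keep)) stop("empty post-burn-in window")
    matrix(r$snapshots[, network, keep],
           nrow = dim(r$snapshots)[1])
  })
  U <- do.call(cbind, mats)
  FU <- firing_rate(U, params)
  data.frame(theta = runs[[1]]$grid$angles,
             mean_u = rowMeans(U),
             var_u = apply(U, 1, var),
             mean_f = rowMeans(FU),
             var_f = apply(FU, 1, var))
}
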