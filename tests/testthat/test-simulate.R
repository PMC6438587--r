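test_that("structured noise increments have the stated covariance", {
  g <- ring_grid(32)
  dt <- 0.01
  ## b = 0: diagonal covariance a/dtheta * dt
  set.seed(501)
  draws <- t(replicate(20000, sample_noise_increment(
    g, noise_params(0.05, 2, 0), dt)))
  cv <- cov(draws)
  expect_equal(mean(diag(cv)), 2 * dt / g$spacing, tolerance = 0.05)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off)), 4 * (2 * dt / g$spacing) / sqrt(20000) * 5)
  ## a = 0: every draw lies in span{cos, sin} (rank <= 2)
  draws2 <- t(replicate(50, sample_noise_increment(
    g, noise_params(0.05, 0, 0.5), dt)))
  expect_lte(qr(draws2)$rank, 2L)
  ## figure parameters: neighbor covariance ~ b cos(dtheta) dt
  set.seed(502)
  draws3 <- t(replicate(40000, sample_noise_increment(
    g, noise_params(0.05, 3, 0.5), dt)))
  cv3 <- cov(draws3)
  lag1 <- mean(cv3[cbind(1:31, 2:32)])
  expect_equal(lag1, 0.5 * cos(g$spacing) * dt, tolerance = 0.15)
  expect_error(sample_noise_increment(g, fig_noise(), 0), "dt")
})

test_that("phase extraction is exact for first-harmonic fields", {
  g <- ring_grid(200)
  u <- 1.85 * cos(g$angles - 0.7)
  expect_equal(extract_phase(u, g), -0.7, tolerance = 1e-12)
  expect_error(extract_phase(rep(2, 200), g), "no bump")
  ## even-harmonic contamination does not bias the estimator
  u2 <- u + 0.4 * cos(2 * g$angles + 0.3)
  expect_equal(extract_phase(u2, g), -0.7, tolerance = 1e-12)
})

test_that("deterministic flow holds the bump stationary", {
  run <- simulate_field(fig_ring(), stimulus_params(0), fig_noise(),
                        duration = 100, noise_on = FALSE,
                        snapshot_every = 50, bumps = fig_bump())
  nt <- dim(run$snapshots)[3]
  expect_lt(max(abs(run$snapshots[, 1, nt] - run$snapshots[, 1, 1])), 1e-6)
  expect_equal(run$phases[, 1], rep(0, nrow(run$phases)), tolerance = 1e-10)
})

test_that("identical seeds give bitwise-identical trajectories", {
  args <- list(fig_ring(), stimulus_params(2), fig_noise(), duration = 3,
               seed = 42, bumps = fig_bump())
  expect_identical(do.call(simulate_field, args)$phases,
                   do.call(simulate_field, args)$phases)
  red <- fig_reduction()
  expect_identical(simulate_phase_sde(red, 20, seed = 7)$phases,
                   simulate_phase_sde(red, 20, seed = 7)$phases)
  expect_false(identical(simulate_phase_sde(red, 20, seed = 7)$phases,
                         simulate_phase_sde(red, 20, seed = 8)$phases))
})

test_that("free reduced phase diffuses with variance slope 2 eps^2 D", {
  red <- phase_reduction(0, diffusion = 1, epsilon = 0.3)
  ens <- ensemble_phase_sde(red, 2000, duration = 10, dt = 0.001,
                            seed = 503, save_every = 0.5)
  v <- apply(ens$unwrapped[[1]], 1, var)
  slope <- coef(lm(v ~ ens$times))[2]
  expect_equal(unname(slope), 2 * 0.3^2 * 1, tolerance = 0.1)
})

test_that("reduced SDE relaxes to the analytic von Mises", {
  ## kappa = Lambda/(eps D) = 2; fast-mixing parameterization
  red <- phase_reduction(1, diffusion = 1, epsilon = 0.5)
  expect_equal(red$kappa, 2)
  ens <- ensemble_phase_sde(red, 50, duration = 400, dt = 0.002,
                            seed = 504, save_every = 1)
  tv <- phase_tv_distance(ens$phases[[1]][ens$times > 50, ],
                          as_von_mises(red))
  expect_lt(tv, 0.05)
})

test_that("halving the time step leaves the stationary histogram unchanged", {
  red <- phase_reduction(2, diffusion = 1, epsilon = 0.5)  # kappa = 4
  tvs <- vapply(c(0.002, 0.001), function(dt) {
    ens <- ensemble_phase_sde(red, 400, duration = 500, dt = dt,
                              seed = 505, save_every = 1)
    phase_tv_distance(ens$phases[[1]][ens$times > 50, ], as_von_mises(red))
  }, numeric(1))
  expect_lt(abs(diff(tvs)), 0.01)
})

test_that("model A coupling binds the phase pair", {
  reds <- build_phase_reduction(list(fig_ring(), fig_ring()),
                                list(stimulus_params(0), stimulus_params(0)),
                                fig_noise(), coupling_params("A", 0, 2),
                                bumps = list(fig_bump(), fig_bump()))
  ens <- ensemble_phase_sde(reds, 200, duration = 150, dt = 0.005,
                            seed = 506, save_every = 5)
  nt <- nrow(ens$phases[[1]])
  d <- wrap_angle(ens$phases[[1]][nt, ] - ens$phases[[2]][nt, ])
  s <- ens$unwrapped[[1]][nt, ] + ens$unwrapped[[2]][nt, ]
  expect_lt(var(d), var(s))
})

test_that("ensemble statistics behave on known inputs", {
  set.seed(507)
  st_unif <- ensemble_stats(runif(20000, -pi, pi))
  expect_lt(st_unif$resultant, 0.03)
  expect_equal(sum(st_unif$histogram$prob), 1)
  beta <- rvm(200000, kappa = 2)
  st_vm <- ensemble_stats(beta)
  expect_equal(Mod(st_vm$moment1), ORACLE$bessel_r1_2, tolerance = 0.01)
  expect_error(ensemble_stats(matrix(1, 2, 2), times = c(1, 2),
                              burn_in = 5), "empty")
})

test_that("field ensemble variance tuning is M-shaped in the driven regime", {
  ## stationary-start ensemble at kappa ~ 2 (hbar = kappa * eps * A * D)
  red <- fig_reduction()
  A <- fig_bump()$amplitude
  hbar <- 2 * 0.05 * A * red$diffusion
  set.seed(508)
  runs <- lapply(seq_len(24), function(k) {
    simulate_field(fig_ring(), stimulus_params(hbar), fig_noise(),
                   duration = 30, seed = 5080 + k,
                   init_phase = rvm(1, 2), snapshot_every = 2,
                   bumps = fig_bump())
  })
  st <- field_tuning_stats(runs, fig_ring(), burn_in = 5)
  th <- st$theta
  flank <- abs(abs(th) - pi / 2) < 0.4
  center <- abs(th) < 0.4
  anti <- abs(abs(th) - pi) < 0.4
  expect_gt(mean(st$var_u[flank]), mean(st$var_u[center]))
  expect_gt(mean(st$var_u[flank]), mean(st$var_u[anti]))
  ## firing-rate variance is bimodal as well
  expect_gt(mean(st$var_f[flank]), mean(st$var_f[center]))
})

test_that("simulation argument guards", {
  expect_error(simulate_field(fig_ring(), stimulus_params(0), fig_noise(),
                              dt = 0.1), "dt")
  expect_error(simulate_phase_sde(list(fig_reduction(), fig_reduction(),
                                       fig_reduction())),
               "at most two")
})
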