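test_that("drift amplitude: closed form, limits, and quadrature route", {
  bump <- fig_bump()
  stim <- stimulus_params(contrast = 2)
  expect_equal(drift_amplitude(stim, bump), 2 / bump$amplitude)
  expect_equal(drift_amplitude(stimulus_params(0), bump), 0)
  expect_error(drift_amplitude(stim, solve_bump(fig_ring())[[1]]),
               "no bump to pin")
  ## adjoint-projection quadrature equals hbar / A
  expect_equal(drift_amplitude_quadrature(stim, bump, n_points = 400),
               2 / bump$amplitude, tolerance = 1e-8)
})

test_that("model A coupling: closed form vs adjoint quadrature", {
  bump <- fig_bump()
  cpl <- coupling_params("A", uniform_component = 1.5,
                         modulated_amplitude = 2)
  K <- coupling_fn_model_a(cpl, bump, bump)
  expect_equal(K(0), 0)
  ## symmetric amplitudes, Jbar = 1: K(pi/2) = Kbar * g(A)/A = Kbar
  expect_equal(K(pi / 2), 2, tolerance = 1e-10)
  betas <- seq(-pi, pi, length.out = 9)
  Kq <- coupling_quadrature_model_a(cpl, bump, bump, betas)
  expect_equal(K(betas), Kq, tolerance = 1e-8)
  ## the uniform kernel component is annihilated by the odd null vector
  cpl0 <- coupling_params("A", uniform_component = 0,
                          modulated_amplitude = 2)
  expect_equal(Kq, coupling_quadrature_model_a(cpl0, bump, bump, betas),
               tolerance = 1e-10)
  expect_error(coupling_fn_model_a(coupling_params("B", 0, 1), bump, bump))
})

test_that("model B coupling: potential symmetry and derivative identity", {
  red <- fig_reduction_b(kbar = 1)
  phi <- red$potential_phi
  K <- red$coupling_fn
  b <- seq(0, pi, length.out = 181)
  expect_equal(phi(-b), phi(b), tolerance = 1e-10)          # even potential
  expect_equal(K(-b), -K(b), tolerance = 1e-8)              # odd coupling
  expect_equal(K(0), 0, tolerance = 1e-12)
  ## frozen potential values (adaptive-quadrature oracle)
  expect_equal(phi(0), ORACLE$phi_at_0, tolerance = 1e-6)
  expect_equal(phi(pi), ORACLE$phi_at_pi, tolerance = 1e-6)
  ## K = -(2 Kbar/(A|Gamma|)) phi'(beta): finite differences on the grid
  bb <- seq(-3, 3, length.out = 41)
  h <- 1e-5
  fd <- -(phi(bb + h) - phi(bb - h)) / (2 * h) * red$kbar_eff
  expect_equal(K(bb), fd, tolerance = 1e-4)
  ## K integrates to zero (oddness)
  th <- ring_grid(720)$angles
  expect_lt(abs(sum(K(th)) * 2 * pi / 720), 1e-8)
  expect_lt(abs(sum(coupling_fn_model_a(coupling_params("A", 0, 2),
                                        fig_bump(), fig_bump())(th)) *
                  2 * pi / 720), 1e-10)
})

test_that("model B potential is von-Mises shaped (recorded fit)", {
  red <- fig_reduction_b(kbar = 1)
  b <- seq(-pi, pi, length.out = 181)
  phi_vals <- red$potential_phi(b)
  ## least-squares fit of c * M(beta; 0, k) + d
  obj <- function(p) {
    vm <- von_mises(exp(p[1]))
    resid <- phi_vals - (p[2] * von_mises_pdf(b, vm) + p[3])
    sum(resid^2)
  }
  fit <- optim(c(log(0.6), 12, -0.9), obj)
  k_hat <- exp(fit$par[1])
  resid_max <- sqrt(max((phi_vals - (fit$par[2] *
    von_mises_pdf(b, von_mises(k_hat)) + fit$par[3]))^2))
  ## recorded, not asserted against the printed (c, d, kappa); we only
  ## require that the fitted von Mises shape describes phi well
  expect_true(is.finite(k_hat) && k_hat > 0)
  expect_lt(resid_max, 0.15)
})

test_that("diffusion coefficient: decomposition, limits, oracle", {
  bump <- fig_bump()
  A <- bump$amplitude
  ## cosine-correlated noise alone: D = b / A^2
  expect_equal(diffusion_coefficient(noise_params(0.05, 0, 0.5), bump),
               0.5 * ORACLE$d_cos_unit, tolerance = 1e-8)
  expect_equal(diffusion_coefficient(noise_params(0.05, 0, 1), bump),
               1 / A^2, tolerance = 1e-8)
  ## figure parameters a = 3, b = 0.5
  expect_equal(diffusion_coefficient(fig_noise(), bump),
               ORACLE$diffusion_fig2, tolerance = 1e-8)
  ## spatially homogeneous correlation contributes nothing (f'(U) even)
  expect_lt(abs(diffusion_coefficient(fig_noise(), bump,
                                      correlation = function(t) 0.7)), 1e-12)
  ## general-correlation double quadrature agrees with the b-route
  expect_equal(diffusion_coefficient(fig_noise(), bump,
                                     correlation = function(t) 0.5 * cos(t)),
               0.5 * ORACLE$d_cos_unit, tolerance = 1e-8)
  ## white-noise term vs an independent double-sum evaluation of the
  ## quadratic form with C = a * delta discretized as a/dtheta on the diagonal
  g <- ring_grid(512)
  V <- bump$adjoint_null(g$angles)
  gam <- sum(V * (-A * sin(g$angles))) * g$spacing
  d_white_direct <- (3 / g$spacing) * sum(V * V) * g$spacing^2 / gam^2
  expect_equal(diffusion_coefficient(noise_params(0.05, 3, 0), bump),
               d_white_direct, tolerance = 1e-8)
  ## stationarity: rotating the adjoint frame leaves D unchanged
  for (s in c(0.7, 2.1)) {
    Vs <- bump$adjoint_null(g$angles + s)
    Cmat <- outer(g$angles, g$angles, function(x, y) 0.5 * cos(x - y))
    d_shift <- drop(t(Vs) %*% Cmat %*% Vs) * g$spacing^2 / gam^2
    expect_equal(d_shift, 0.5 * ORACLE$d_cos_unit, tolerance = 1e-8)
  }
})

test_that("build_phase_reduction packages coefficients consistently", {
  red <- fig_reduction(contrast = 2)
  expect_equal(red$drift_amplitude, 2 / fig_bump()$amplitude)
  expect_equal(red$diffusion, ORACLE$diffusion_fig2, tolerance = 1e-8)
  expect_identical(red$coupling_model, "none")
  expect_equal(red$coupling_fn(seq(-3, 3)), rep(0, 7))
  ## kappa = hbar / (eps * A * D)
  expect_equal(red$kappa,
               2 / (0.05 * fig_bump()$amplitude * red$diffusion),
               tolerance = 1e-10)
  ## model A symmetric pair: both reductions carry K(beta) = Kbar sin(beta)
  reds <- build_phase_reduction(list(fig_ring(), fig_ring()),
                                list(stimulus_params(0.2),
                                     stimulus_params(0.2)),
                                fig_noise(), coupling_params("A", 0, 2),
                                bumps = list(fig_bump(), fig_bump()))
  expect_equal(reds[[1]]$coupling_fn(0.4), 2 * sin(0.4), tolerance = 1e-8)
  expect_equal(reds[[1]]$chi, 2 / (0.05 * reds[[1]]$diffusion),
               tolerance = 1e-8)
  ## no stable bump: error propagates
  expect_error(
    suppressWarnings(build_phase_reduction(ring_params(0.2, 4, 0.5),
                                           stimulus_params(1), fig_noise())),
    "no stable")
  ## direct constructor
  pr <- phase_reduction(1.5, 0.5, epsilon = 0.5)
  expect_equal(pr$kappa, 1.5 / (0.5 * 0.5))
  expect_error(phase_reduction(-1, 1), "invalid")
})

test_that("reduction serializes to JSON", {
  js <- reduction_to_json(fig_reduction_b(), n_beta = 21)
  obj <- jsonlite::fromJSON(js)
  expect_equal(obj$diffusion, ORACLE$diffusion_fig2, tolerance = 1e-8)
  expect_identical(nrow(obj$samples), 21L)
  expect_true(all(is.finite(obj$samples$phi)))
})
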