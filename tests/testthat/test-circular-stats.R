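quad_norm <- function(pdf_fun, n = 2048) {
  g <- ring_grid(n)
  sum(pdf_fun(g$angles)) * g$spacing
}

test_that("von Mises density: normalization, uniform and Gaussian limits", {
  expect_equal(von_mises_pdf(c(-2, 0, 1), von_mises(0)),
               rep(1 / (2 * pi), 3))
  for (k in c(0.5, 2, 10, 200)) {
    expect_equal(quad_norm(function(b) von_mises_pdf(b, von_mises(k))), 1,
                 tolerance = 1e-10)
  }
  ## large kappa: normal with sigma^2 = 1/kappa near the center
  k <- 400
  b <- c(-0.05, 0, 0.05)
  expect_equal(von_mises_pdf(b, von_mises(k)),
               dnorm(b, 0, 1 / sqrt(k)), tolerance = 1e-2)
  ## center handling
  expect_equal(von_mises_pdf(1.2, von_mises(3, center = 1.2)),
               von_mises_pdf(0, von_mises(3)))
})

test_that("circular moments are Bessel ratios", {
  expect_identical(circular_moment(0, von_mises(2)), 1 + 0i)
  expect_equal(circular_moment(1, von_mises(2)),
               complex(real = ORACLE$bessel_r1_2), tolerance = 1e-12)
  ## direct quadrature of <exp(i n beta)>
  g <- ring_grid(2048)
  for (n in 1:3) {
    mq <- sum(exp(1i * n * g$angles) *
                von_mises_pdf(g$angles, von_mises(2, 0.6))) * g$spacing
    expect_equal(circular_moment(n, von_mises(2, 0.6)), mq,
                 tolerance = 1e-10)
  }
  expect_equal(Mod(circular_moment(2, von_mises(0))), 0)
  expect_true(all(vapply(0:5, function(n)
    Mod(circular_moment(n, von_mises(7))), numeric(1)) <= 1))
  expect_error(circular_moment(-1, von_mises(1)))
})

test_that("mean tuning amplitude: limits and monotonicity", {
  th <- seq(-pi, pi, length.out = 41)
  expect_equal(tuning_mean(th, 1.85, von_mises(0)), rep(0, 41))
  expect_equal(tuning_mean(th, 1.85, von_mises(1e5)), 1.85 * cos(th),
               tolerance = 1e-3)
  amp <- vapply(seq(0, 20, by = 0.5), function(k)
    tuning_mean(0, 1, von_mises(k)), numeric(1))
  expect_true(all(diff(amp) > 0))
})

test_that("variance tuning: flat at kappa = 0, M-shaped for kappa > 0", {
  A <- 1.85
  th <- seq(-pi, pi, length.out = 181)
  expect_equal(tuning_variance(th, A, von_mises(0)), rep(A^2 / 2, 181))
  v <- tuning_variance(th, A, von_mises(2))
  expect_true(all(v >= 0))
  expect_equal(v, tuning_variance(th + pi, A, von_mises(2)))  # pi-periodic
  expect_gt(tuning_variance(pi / 2, A, von_mises(2)),
            tuning_variance(0, A, von_mises(2)))
  expect_equal(which.max(v), which.min(abs(th + pi / 2)))     # maxima at ±pi/2
})

test_that("variance tuning matches Monte-Carlo sampling", {
  set.seed(401)
  A <- 1.85
  beta <- rvm(1e6, kappa = 2)
  for (th in c(0, pi / 4, pi / 2)) {
    u <- A * cos(th + beta)
    se <- sd((u - mean(u))^2) / sqrt(length(u))
    expect_lt(abs(var(u) - tuning_variance(th, A, von_mises(2))), 3 * se)
  }
})

test_that("firing-rate variance: symmetry, positivity, sampling oracle", {
  rp <- fig_ring()
  A <- fig_bump()$amplitude
  th <- seq(-pi, pi, length.out = 61)
  v0 <- firing_rate_variance(th, A, von_mises(0), rp)
  expect_lt(diff(range(v0)), 1e-10)                  # rotationally symmetric
  v2 <- firing_rate_variance(th, A, von_mises(2), rp)
  expect_true(all(v2 >= 0))
  set.seed(402)
  beta <- rvm(1e6, kappa = 2)
  for (t1 in c(0, pi / 3)) {
    fu <- firing_rate(A * cos(t1 + beta), rp)
    se <- sd((fu - mean(fu))^2) / sqrt(length(fu))
    expect_lt(abs(var(fu) - firing_rate_variance(t1, A, von_mises(2), rp)),
              3 * se)
  }
})

test_that("bivariate normalization: closed cases and quadrature oracle", {
  expect_equal(bivariate_normalization(0, 0, 0), (2 * pi)^2)
  expect_equal(bivariate_normalization(1.3, 2.2, 0),
               (2 * pi)^2 * besselI(1.3, 0) * besselI(2.2, 0),
               tolerance = 1e-12)
  expect_equal(bivariate_cosine_model(1, 2, 5)$normalization,
               ORACLE$biv_norm_125, tolerance = 1e-10)
  expect_error(bivariate_normalization(-1, 2, 0))
})

test_that("joint density and marginal integrate correctly", {
  for (chi in c(-1, 0, 5)) {
    m <- bivariate_cosine_model(1, 2, chi)
    ## joint density normalization by the moments engine
    expect_equal(bivariate_moments(m, 241)$norm_quad, m$normalization,
                 tolerance = 1e-10)
    ## marginal integrates to 1
    expect_equal(quad_norm(function(b) bivariate_marginal(b, m)), 1,
                 tolerance = 1e-8)
    ## marginal is even
    b <- seq(0, pi, length.out = 31)
    expect_equal(bivariate_marginal(b, m), bivariate_marginal(-b, m),
                 tolerance = 1e-12)
    ## marginal equals direct quadrature of the joint over beta2
    g <- ring_grid(721)
    for (b1 in c(-2, 0.3, 1.7)) {
      direct <- sum(bivariate_pdf(b1, g$angles, m)) * g$spacing
      expect_equal(bivariate_marginal(b1, m), direct, tolerance = 1e-8)
    }
  }
  ## chi = 0 reduces to the plain von Mises marginal
  m0 <- bivariate_cosine_model(1.5, 2.5, 0)
  b <- seq(-pi, pi, length.out = 41)
  expect_equal(bivariate_marginal(b, m0),
               von_mises_pdf(b, von_mises(1.5)), tolerance = 1e-10)
})

test_that("modality classification follows the printed conditions", {
  expect_identical(modality(2, 2, -0.5), "unimodal")   # 0.5 < 1
  expect_identical(modality(3, 3, -2), "bimodal")      # 2 > 1.5, kappas > 2
  expect_identical(modality(2, 2, -1), "boundary")
  for (chi in c(0, 0.1, 5)) expect_identical(modality(1, 7, chi), "unimodal")
  ## -chi exceeds the harmonic bound but kappas do not exceed -chi
  expect_identical(modality(1, 1, -4), "unimodal")
  expect_error(modality(0, 1, 0))
})

test_that("Gaussian approximation matches the covariance algebra", {
  ga <- gaussian_approx(3, 5, 0)
  expect_equal(ga$covariance, diag(c(1 / 3, 1 / 5)))
  ## symmetric case: var = (1/kappa) (kappa + chi)/(kappa + 2 chi)
  ga2 <- gaussian_approx(1, 1, 5)
  expect_equal(ga2$covariance[1, 1], 6 / 11, tolerance = 1e-12)
  expect_lt(ga2$covariance[1, 1], 1)                   # < 1/kappa
  expect_equal(ga2$covariance %*% ga2$precision, diag(2),
               tolerance = 1e-12)
  expect_error(gaussian_approx(0.1, 0.1, -1), "positive definite")
})

test_that("Gaussian approximation improves with concentration", {
  ## total-variation distance between the exact bivariate density and
  ## N2(0, Sigma), both restricted to the torus fundamental domain
  tv_gauss <- function(kappa) {
    m <- bivariate_cosine_model(kappa, kappa, 1)
    ga <- gaussian_approx(kappa, kappa, 1)
    g <- ring_grid(241)
    b <- g$angles
    P <- outer(b, b, function(x, y) bivariate_pdf(x, y, m))
    Sinv <- ga$precision
    dets <- Sinv[1, 1] * Sinv[2, 2] - Sinv[1, 2]^2
    Q <- outer(b, b, function(x, y) {
      exp(-0.5 * (Sinv[1, 1] * x^2 + 2 * Sinv[1, 2] * x * y +
                    Sinv[2, 2] * y^2)) * sqrt(dets) / (2 * pi)
    })
    0.5 * sum(abs(P - Q)) * g$spacing^2
  }
  tvs <- vapply(c(4, 16, 64), tv_gauss, numeric(1))
  expect_true(all(diff(tvs) < 0))
})

test_that("coupling suppresses phase variance; single-ring limit is exact", {
  vars <- vapply(c(0, 1, 5), function(chi)
    bivariate_moments(bivariate_cosine_model(2, 2, chi))$var_beta1,
    numeric(1))
  expect_true(all(diff(vars) < 0))
  ## chi = 0: every bivariate statistic equals its univariate counterpart
  mo <- bivariate_moments(bivariate_cosine_model(2, 2, 0))
  expect_equal(mo$c1, ringwander:::bessel_ratio(1, 2), tolerance = 1e-8)
  expect_equal(mo$cos2_1, ringwander:::bessel_ratio(2, 2), tolerance = 1e-8)
  expect_equal(mo$cc, mo$c1 * mo$c2, tolerance = 1e-8)
  expect_lt(abs(mo$ss), 1e-8)
})

test_that("model A tuning statistics: single-ring limit and sampling oracle", {
  A <- 1.85
  th <- seq(-pi, pi, length.out = 25)
  st0 <- model_a_tuning_stats(th, A, bivariate_cosine_model(2, 2, 0))
  expect_equal(st0$mean, tuning_mean(th, A, von_mises(2)), tolerance = 1e-8)
  expect_equal(st0$variance, tuning_variance(th, A, von_mises(2)),
               tolerance = 1e-8)
  expect_true(all(abs(st0$correlation) < 1e-7))
  ## sampling oracle at (kappa = 2, chi = 5): draw beta1 from the marginal
  ## (inverse CDF), then beta2 | beta1 is von Mises
  set.seed(403)
  m <- bivariate_cosine_model(2, 2, 5)
  n <- 1e6
  grid <- seq(-pi, pi, length.out = 4097)
  pdf1 <- bivariate_marginal(grid, m)
  cdf <- cumsum(pdf1) - pdf1[1]
  cdf <- cdf / cdf[length(cdf)]
  b1 <- approx(cdf, grid, runif(n), ties = "ordered")$y
  conc <- Mod(2 + 5 * exp(1i * b1))
  cent <- Arg(2 + 5 * exp(1i * b1))
  ## von Mises draws with per-sample concentration via a uniform trick:
  ## bucket kappa into a fine grid and sample within buckets
  b2 <- numeric(n)
  kb <- round(conc * 50)
  for (k in unique(kb)) {
    idx <- which(kb == k)
    b2[idx] <- wrap_angle(rvm(length(idx), k / 50) + cent[idx])
  }
  mo <- bivariate_moments(m)
  for (pair in list(c("c1", NA), c("cc", NA), c("ss", NA))) {
    nm <- pair[1]
    emp <- switch(nm, c1 = cos(b1), cc = cos(b1) * cos(b2),
                  ss = sin(b1) * sin(b2))
    se <- sd(emp) / sqrt(n)
    expect_lt(abs(mean(emp) - mo[[nm]]), 4 * se + 2e-3)
  }
})

test_that("model B center statistics reproduce surround modulation", {
  red <- fig_reduction_b()
  biases <- c(0, pi)
  st_neg <- model_b_center_stats(biases, 1, -1, red)
  st_pos <- model_b_center_stats(biases, 1, 1, red)
  st_0 <- model_b_center_stats(biases, 1, 0, red)
  ## chi = 0: independent of the surround bias
  expect_lt(diff(range(st_0$variance)), 1e-10)
  expect_lt(diff(range(st_0$mean)), 1e-10)
  ## inhibitory coupling: variance facilitated at aligned biases
  expect_gt(st_neg$variance[1], st_neg$variance[2])
  expect_gt(st_neg$variance[1], st_0$variance[1])     # above baseline at 0
  expect_lt(st_neg$variance[2], st_0$variance[2])     # below baseline at pi
  ## excitatory coupling: reversed
  expect_lt(st_pos$variance[1], st_pos$variance[2])
  ## mean and variance covary in opposite directions
  expect_lt((st_neg$mean[1] - st_neg$mean[2]) *
              (st_neg$variance[1] - st_neg$variance[2]), 0)
  expect_lt((st_pos$mean[1] - st_pos$mean[2]) *
              (st_pos$variance[1] - st_pos$variance[2]), 0)
  ## equal-diffusivity guard on the stationary-density constructor
  r1 <- phase_reduction(1, 0.5)
  r2 <- phase_reduction(1, 0.9)
  expect_error(bivariate_from_reductions(r1, r2), "equal diffusivities")
  expect_s3_class(bivariate_from_reductions(r1, r1),
                  "bivariate_cosine_model")
})

test_that("model B density normalizes and is continuous in chi", {
  red <- fig_reduction_b()
  dens <- model_b_density(1, -1, c(0, 1), red)
  g <- dens$grid
  expect_equal(sum(dens$density_grid) * g$spacing^2, 1, tolerance = 1e-8)
  ## chi -> 0 recovers the product of independent von Mises densities
  dens0 <- model_b_density(1, 0, c(0, 0.5), red)
  p_direct <- von_mises_pdf(0.3, von_mises(1)) *
    von_mises_pdf(-0.2, von_mises(1, center = -0.5))
  expect_equal(dens0$pdf(0.3, -0.2), p_direct, tolerance = 1e-6)
})
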