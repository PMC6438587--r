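## Shared fixtures, memoized so that expensive objects (bump solutions,
## reductions, the model-B potential) are built once per test run.
.fx <- new.env(parent = emptyenv())

fig_ring <- function() ring_params(weight_amplitude = 1, gain = 4,
                                   threshold = 0.5)
fig_noise <- function() noise_params(epsilon = 0.05, white_weight = 3,
                                     cosine_weight = 0.5)

fig_bump <- function() {
  if (is.null(.fx$bump)) {
    sols <- solve_bump(fig_ring())
    .fx$bump <- Filter(function(b) b$is_stable && b$amplitude > 0, sols)[[1]]
  }
  .fx$bump
}

fig_reduction <- function(contrast = 2) {
  key <- paste0("red_", contrast)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_phase_reduction(fig_ring(),
                                        stimulus_params(contrast),
                                        fig_noise(), bumps = fig_bump())
  }
  .fx[[key]]
}

fig_reduction_b <- function(kbar = 1) {
  key <- paste0("redb_", kbar)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_phase_reduction(fig_ring(), stimulus_params(2),
                                        fig_noise(),
                                        coupling_params("B", 0, kbar),
                                        bumps = fig_bump())
  }
  .fx[[key]]
}

## Frozen oracle values (independent high-precision adaptive quadrature /
## closed forms; see test comments for the defining expressions).
ORACLE <- list(
  f_at_185 = 0.9955037268390589,          # 1 / (1 + exp(-5.4))
  bump_amplitude = 1.8499618857323503,    # root of A = g(A), gamma = 4
  lambda_even = -0.8178637253414789,      # Eq: 2[J int_0^pi f'(U) - 1]
  high_gain_stable = sqrt(1.5) + sqrt(0.5),
  high_gain_unstable = sqrt(1.5) - sqrt(0.5),
  bessel_r1_2 = 0.697774657964008,        # I1(2)/I0(2)
  diffusion_fig2 = 0.7457100407045864,    # a=3, b=0.5 at the gamma=4 bump
  d_cos_unit = 0.29219611567189935,       # 1/A^2
  biv_norm_125 = 4964.176110958587,       # N(1, 2, 5) by 2-D quadrature
  phi_at_0 = 2.2750551719545142,
  phi_at_pi = 0.021306832889427675)

## von Mises sampler by numeric inverse-CDF (oracle-side, independent of
## the package's SDE machinery)
rvm <- function(n, kappa, center = 0) {
  grid <- seq(-pi, pi, length.out = 4097)
  pdf <- exp(kappa * (cos(grid) - 1))
  cdf <- cumsum(pdf) - pdf[1]
  cdf <- cdf / cdf[length(cdf)]
  wrap_angle(approx(cdf, grid, runif(n), ties = "ordered")$y + center)
}

## unwrap a wrapped phase series by mapping increments to (-pi, pi]
unwrap_phases <- function(beta) cumsum(c(beta[1], wrap_angle(diff(beta))))
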