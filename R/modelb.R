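#' Stationary joint density for horizontally coupled rings (model B)
#'
#' For the patchy delta-kernel architecture the stationary joint phase
#' density generalizes the cosine model:
#' \deqn{p(\beta_1, \beta_2) = M^{-1}\exp\{\kappa\cos(\beta_1+\bar\theta_1)
#'   + \kappa\cos(\beta_2+\bar\theta_2) + \chi\,\phi(\beta_1-\beta_2)\},}
#' where \eqn{\phi} is the even overlap potential of the two bumps (from
#' [coupling_fn_model_b()] or a `phase_reduction`) and the normalization
#' `M` has no closed form (always numerical, since \eqn{\phi} is only
#' available as a table).
#'
#' @param kappa stimulus concentration \eqn{\kappa \ge 0} (equal for the
#'   two networks).
#' @param chi coupling strength (sign encodes net excitatory `> 0` or
#'   inhibitory `< 0` horizontal connections).
#' @param biases length-2 vector of stimulus biases
#'   \eqn{(\bar\theta_1, \bar\theta_2)}.
#' @param phi the potential: a function of the phase difference, or a
#'   `phase_reduction` carrying one.
#' @param n_grid quadrature resolution per dimension.
#' @return an object of class `model_b_density` with the normalization and
#'   a `pdf(beta1, beta2)` function.
#' @export
model_b_density <- function(kappa, chi, biases = c(0, 0), phi,
                            n_grid = 241L) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (inherits(phi, "phase_reduction")) {
    if (is.null(phi$potential_phi))
      stop("this phase_reduction carries no model-B potential")
    phi <- phi$potential_phi
  }
  g <- ring_grid(n_grid)
  b <- g$angles
  phi_max <- max(phi(b))
  logp <- function(b1, b2) {
    kappa * cos(b1 + biases[1]) + kappa * cos(b2 + biases[2]) +
      chi * phi(wrap_angle(b1 - b2))
  }
  shift <- 2 * kappa + abs(chi) * phi_max
  P <- exp(outer(b, b, logp) - shift)
  M <- sum(P) * g$spacing^2 * exp(shift)
  pdf <- function(beta1, beta2) exp(logp(beta1, beta2) - shift) /
    (M * exp(-shift))
  structure(list(kappa = kappa, chi = chi, biases = biases, phi = phi,
                 normalization = M, pdf = pdf, grid = g,
                 density_grid = P * exp(shift) / M),
            class = "model_b_density")
}

## First/second circular harmonic moments of beta1 under a model-B density.
model_b_moments <- function(dens) {
  b <- dens$grid$angles
  P <- dens$density_grid
  w <- dens$grid$spacing^2
  Z <- sum(P) * w
  ones <- rep(1, length(b))
  avg <- function(v1) sum(outer(v1, ones) * P) * w / Z
  list(c1 = avg(cos(b)), s1 = avg(sin(b)),
       c2 = avg(cos(2 * b)), s2 = avg(sin(2 * b)))
}

#' Center-network statistics as a function of the surround bias
#'
#' Network 1 ("center") is driven at bias 0; network 2 ("surround") is
#' driven at bias \eqn{\bar\theta}.  For each surround bias this computes
#' the first and second circular harmonic moments of \eqn{\beta_1} under
#' the model-B stationary density and assembles the exact normalized mean
#' and variance tuning of the center:
#' \deqn{\langle U_1\rangle(\theta)/A = \langle\cos\beta_1\rangle\cos\theta
#'   - \langle\sin\beta_1\rangle\sin\theta,}
#' \deqn{\mathrm{var}(U_1)(\theta)/A^2 = \tfrac12[1 +
#'   \langle\cos2\beta_1\rangle\cos2\theta -
#'   \langle\sin2\beta_1\rangle\sin2\theta] -
#'   (\langle U_1\rangle(\theta)/A)^2.}
#' Reported are the peak normalized mean (the resultant
#' \eqn{|\langle e^{i\beta_1}\rangle|}) and the maximal normalized
#' variance over \eqn{\theta} (attained near \eqn{\theta = \pm\pi/2}).
#' The sine moments vanish when the surround bias is 0 or \eqn{\pi}, in
#' which case these reduce to the cosine-only expressions.
#'
#' Qualitatively: for net inhibitory horizontal coupling (\eqn{\chi < 0})
#' the center variance is facilitated relative to the \eqn{\chi = 0}
#' baseline when the two stimuli have similar biases and suppressed when
#' they are opposed; the converse holds for \eqn{\chi > 0}; and the mean
#' and variance covary in opposite directions.
#'
#' @param surround_bias vector of surround bias angles \eqn{\bar\theta}.
#' @param kappa stimulus concentration (`>= 0`).
#' @param chi coupling strength.
#' @param reduction a `phase_reduction` carrying the model-B potential
#'   (or a bare potential function).
#' @param n_grid quadrature resolution per dimension.
#' @param n_theta resolution of the preference-angle scan for the
#'   variance maximum.
#' @return a data.frame with columns `surround_bias`, `mean`, `variance`
#'   (both normalized).
#' @export
model_b_center_stats <- function(surround_bias, kappa, chi, reduction,
                                 n_grid = 241L, n_theta = 181L) {
  phi <- if (inherits(reduction, "phase_reduction")) {
    if (is.null(reduction$potential_phi))
      stop("this phase_reduction carries no model-B potential")
    reduction$potential_phi
  } else reduction
  theta <- seq(-pi, pi, length.out = n_theta)
  out <- lapply(surround_bias, function(tb) {
    dens <- model_b_density(kappa, chi, biases = c(0, tb), phi, n_grid)
    mo <- model_b_moments(dens)
    mean_curve <- mo$c1 * cos(theta) - mo$s1 * sin(theta)
    second <- 0.5 * (1 + mo$c2 * cos(2 * theta) - mo$s2 * sin(2 * theta))
    var_curve <- second - mean_curve^2
    data.frame(surround_bias = tb,
               mean = sqrt(mo$c1^2 + mo$s1^2),
               variance = max(var_curve))
  })
  do.call(rbind, out)
}
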