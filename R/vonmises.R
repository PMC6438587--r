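#' Von Mises distribution object
#'
#' The stationary density of the reduced single-network phase equation is
#' the von Mises distribution
#' \eqn{M(\beta; \beta^*, \kappa) = e^{\kappa\cos(\beta-\beta^*)} /
#' (2\pi I_0(\kappa))} with concentration \eqn{\kappa \ge 0} and center
#' \eqn{\beta^*}.
#'
#' @param concentration concentration \eqn{\kappa \ge 0}.
#' @param center center angle \eqn{\beta^*}.
#' @return an object of class `von_mises`.
#' @export
von_mises <- function(concentration, center = 0) {
  stop_if_not_scalar(concentration, "concentration")
  if (concentration < 0) stop("'concentration' must be >= 0")
  structure(list(concentration = concentration, center = wrap_angle(center)),
            class = "von_mises")
}

#' Von Mises distribution implied by a phase reduction
#'
#' The stationary phase density of a reduced single ring: concentration
#' \eqn{\kappa = \Lambda/(\epsilon D) = \bar h/(\epsilon A D)} centered at
#' minus the stimulus bias.
#'
#' @param reduction a `phase_reduction`.
#' @return a [von_mises()] object.
#' @export
as_von_mises <- function(reduction) {
  stopifnot(inherits(reduction, "phase_reduction"))
  center <- if (is.null(reduction$stimulus)) 0 else -reduction$stimulus$bias
  von_mises(reduction$kappa, center)
}

## Scaled Bessel ratio I_n(kappa) / I_0(kappa); exp-scaled evaluations keep
## this finite for large kappa (overflow guard for kappa > ~700).
bessel_ratio <- function(n, kappa) {
  if (kappa == 0) return(as.numeric(n == 0))
  besselI(kappa, n, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Von Mises probability density
#'
#' @param beta angle(s) at which to evaluate.
#' @param vm a [von_mises()] object.
#' @return density values; `1/(2*pi)` everywhere when `kappa = 0`.
#' @export
von_mises_pdf <- function(beta, vm) {
  k <- vm$concentration
  ## scaled form avoids overflow of exp(kappa) for large kappa
  exp(k * (cos(beta - vm$center) - 1)) /
    (2 * pi * besselI(k, 0, expon.scaled = TRUE))
}

#' Circular moments of the von Mises distribution
#'
#' \eqn{\mu_n = \langle e^{in\beta}\rangle =
#' (I_n(\kappa)/I_0(\kappa))\, e^{in\beta^*}}; `n = 0` gives 1, and the
#' modulus is always in `[0, 1]`.
#'
#' @param n moment order (integer `>= 0`).
#' @param vm a [von_mises()] object.
#' @return a complex scalar.
#' @export
circular_moment <- function(n, vm) {
  if (n < 0 || n != round(n)) stop("'n' must be a nonnegative integer")
  bessel_ratio(n, vm$concentration) * exp(1i * n * vm$center)
}

#' Mean population tuning curve under phase wandering
#'
#' Averaging the wandering bump \eqn{A\cos(\theta + \beta)} over the
#' stationary phase density gives \eqn{\langle U\rangle(\theta) =
#' A(\kappa)\cos\theta} with mean amplitude
#' \eqn{A(\kappa) = A\, I_1(\kappa)/I_0(\kappa)}, monotonically increasing
#' in \eqn{\kappa} and vanishing at \eqn{\kappa = 0} (spontaneous regime).
#'
#' @param theta preference angle(s) (stimulus-aligned frame; `vm` centered
#'   at 0).
#' @param A bump amplitude.
#' @param vm a [von_mises()] object.
#' @return mean activity at each `theta`.
#' @export
tuning_mean <- function(theta, A, vm) {
  A * bessel_ratio(1, vm$concentration) * cos(theta)
}

#' Variance tuning curve under phase wandering
#'
#' \deqn{\mathrm{var}(U)(\theta) = \frac{A^2}{2}\Big\{1 - r_1^2 -
#'   \big[r_1^2 - r_2\big]\cos 2\theta\Big\},\quad
#'   r_n = I_n(\kappa)/I_0(\kappa).}
#' Flat at \eqn{A^2/2} for \eqn{\kappa = 0}; for \eqn{\kappa > 0} the
#' curve is M-shaped: maxima flank the stimulus at \eqn{\theta = \pm\pi/2}
#' and the minimum sits at the preferred direction \eqn{\theta = 0}.
#'
#' @inheritParams tuning_mean
#' @return variance of the activity at each `theta` (nonnegative,
#'   pi-periodic).
#' @export
tuning_variance <- function(theta, A, vm) {
  r1 <- bessel_ratio(1, vm$concentration)
  r2 <- bessel_ratio(2, vm$concentration)
  (A^2 / 2) * (1 - r1^2 - (r1^2 - r2) * cos(2 * theta))
}

#' Variance tuning of the firing rate
#'
#' Variance of \eqn{f(A\cos(\theta + \beta))} under the von Mises phase
#' density, by quadrature in \eqn{\beta}.  Unlike the activity variance
#' this has higher harmonic content, but in the marginal regime it remains
#' bimodally tuned.
#'
#' @inheritParams tuning_mean
#' @param params a [ring_params()] supplying the sigmoid.
#' @param n_points quadrature resolution in `beta`.
#' @return variance of the firing rate at each `theta`.
#' @export
firing_rate_variance <- function(theta, A, vm, params, n_points = 361L) {
  grid <- ring_grid(n_points)
  b <- grid$angles
  w <- von_mises_pdf(b, vm) * grid$spacing
  vapply(theta, function(t1) {
    fvals <- firing_rate(A * cos(t1 + b), params)
    m1 <- sum(fvals * w)
    max(sum(fvals^2 * w) - m1^2, 0)
  }, numeric(1))
}
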