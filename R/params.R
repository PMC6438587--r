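#' Intrinsic parameters of one ring network
#'
#' A ring network is a population of rate neurons indexed by a periodic
#' stimulus-preference angle \eqn{\theta \in [-\pi, \pi)} with
#' rotation-symmetric recurrent weights \eqn{J(\theta) = \bar J \cos\theta}
#' and a sigmoidal firing-rate function
#' \eqn{f(u) = f_0 / (1 + e^{-\gamma(u - \eta)})}.
#'
#' @param weight_amplitude recurrent weight amplitude \eqn{\bar J \ge 0}.
#' @param gain sigmoid gain \eqn{\gamma > 0}.
#' @param threshold sigmoid threshold \eqn{\eta}.
#' @param max_rate maximal firing rate \eqn{f_0 > 0}.  The analysis-facing
#'   default is the dimensionless value 1; a physical rate (e.g. 100
#'   spikes/sec) is a display scaling only and must not enter the bump
#'   fixed-point solve.
#' @param time_constant membrane/synaptic time constant \eqn{\tau} in ms,
#'   used only to label simulation times; integration is in units of
#'   \eqn{\tau}.
#' @return an object of class `ring_params`.
#' @examples
#' rp <- ring_params(weight_amplitude = 1, gain = 4, threshold = 0.5)
#' firing_rate(rp$threshold, rp)  # sigmoid midpoint: f0/2
#' @export
ring_params <- function(weight_amplitude = 1, gain = 4, threshold = 0.5,
                        max_rate = 1, time_constant = 10) {
  stop_if_not_scalar(weight_amplitude, "weight_amplitude")
  stop_if_not_scalar(gain, "gain")
  stop_if_not_scalar(threshold, "threshold")
  stop_if_not_scalar(max_rate, "max_rate")
  stop_if_not_scalar(time_constant, "time_constant")
  if (weight_amplitude < 0) stop("'weight_amplitude' must be >= 0")
  if (gain <= 0) stop("'gain' must be > 0")
  if (max_rate <= 0) stop("'max_rate' must be > 0")
  if (time_constant <= 0) stop("'time_constant' must be > 0")
  structure(list(weight_amplitude = weight_amplitude, gain = gain,
                 threshold = threshold, max_rate = max_rate,
                 time_constant = time_constant),
            class = "ring_params")
}

#' @export
print.ring_params <- function(x, ...) {
  cat(sprintf(
    "ring_params: Jbar = %g, gain = %g, threshold = %g, f0 = %g, tau = %g ms\n",
    x$weight_amplitude, x$gain, x$threshold, x$max_rate, x$time_constant))
  invisible(x)
}

#' External stimulus parameters
#'
#' The stimulus to a ring network is the weakly biased input
#' \eqn{h(\theta) = \bar h \cos(\theta - \bar\theta)} with contrast
#' \eqn{\bar h \ge 0} and bias angle \eqn{\bar\theta}.
#'
#' @param contrast stimulus contrast \eqn{\bar h \ge 0}.
#' @param bias stimulus bias angle in radians; wrapped to `[-pi, pi)`.
#' @return an object of class `stimulus_params`.
#' @export
stimulus_params <- function(contrast = 0, bias = 0) {
  stop_if_not_scalar(contrast, "contrast")
  stop_if_not_scalar(bias, "bias")
  if (contrast < 0) stop("'contrast' must be >= 0")
  structure(list(contrast = contrast, bias = wrap_angle(bias)),
            class = "stimulus_params")
}

#' Spatially structured noise parameters
#'
#' The additive noise entering the field equations has spatial correlation
#' \eqn{C(\theta) = a\,\delta(\theta) + b\cos(\theta)}: a spatially white
#' component of weight `a` plus a smooth first-harmonic component of weight
#' `b` (colored in \eqn{\theta}, white in time).  The overall noise term is
#' scaled by \eqn{\sqrt{2\epsilon}}.
#'
#' @param epsilon weak-noise scale factor \eqn{\epsilon \in (0, 1)}.
#' @param white_weight weight `a >= 0` of the delta-correlated component.
#' @param cosine_weight weight `b >= 0` of the cosine-correlated component.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(epsilon = 0.05, white_weight = 3,
                         cosine_weight = 0.5) {
  stop_if_not_scalar(epsilon, "epsilon")
  stop_if_not_scalar(white_weight, "white_weight")
  stop_if_not_scalar(cosine_weight, "cosine_weight")
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must be in (0, 1)")
  if (white_weight < 0 || cosine_weight < 0)
    stop("noise weights 'a' and 'b' must be >= 0 (covariance not positive semidefinite otherwise)")
  structure(list(epsilon = epsilon, white_weight = white_weight,
                 cosine_weight = cosine_weight),
            class = "noise_params")
}

#' Inter-network coupling parameters
#'
#' Two coupled-ring architectures are supported.  Model A (interlaminar,
#' "vertical") uses the smooth kernel
#' \eqn{K(\theta) = E + \bar K \cos(\theta)}; model B (intralaminar,
#' "horizontal", patchy like-to-like) uses the delta kernel
#' \eqn{K(\theta) = \bar K\,\delta(\theta)}.
#'
#' @param model one of `"none"`, `"A"`, `"B"`.
#' @param uniform_component uniform kernel component `E` (model A only;
#'   it is annihilated by the odd adjoint null vector and so never enters
#'   the phase dynamics).
#' @param modulated_amplitude modulated amplitude \eqn{\bar K}.
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(model = c("none", "A", "B"),
                            uniform_component = 0,
                            modulated_amplitude = 0) {
  model <- match.arg(model)
  stop_if_not_scalar(uniform_component, "uniform_component")
  stop_if_not_scalar(modulated_amplitude, "modulated_amplitude")
  if (model == "none") {
    uniform_component <- 0
    modulated_amplitude <- 0
  }
  if (model == "B") uniform_component <- 0
  structure(list(model = model, uniform_component = uniform_component,
                 modulated_amplitude = modulated_amplitude),
            class = "coupling_params")
}

#' Discretized ring grid
#'
#' Equispaced angles \eqn{\theta_i = -\pi + i\Delta\theta}, half-open on
#' `[-pi, pi)`, with periodic indexing.  The default `n_points = 200`
#' corresponds to the standard orientation step \eqn{\Delta\theta = 0.01\pi}.
#'
#' @param n_points number of grid points (integer, at least 8).
#' @return an object of class `ring_grid` with fields `n_points`, `angles`
#'   and `spacing`.
#' @export
ring_grid <- function(n_points = 200L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 8L) stop("'n_points' must be >= 8")
  spacing <- 2 * pi / n_points
  structure(list(n_points = n_points,
                 angles = -pi + (seq_len(n_points) - 1L) * spacing,
                 spacing = spacing),
            class = "ring_grid")
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("ring_grid: %d points on [-pi, pi), spacing = %.5f (%.3f * pi)\n",
              x$n_points, x$spacing, x$spacing / pi))
  invisible(x)
}
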