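## Bessel I_s(x) honoring the sign of x: I_s(-x) = (-1)^s I_s(x).
## exp-scaled to keep products finite at large arguments.
bessel_signed_scaled <- function(s, x) {
  v <- besselI(abs(x), s, expon.scaled = TRUE)
  if (x < 0 && s %% 2 == 1) -v else v
}

#' Normalization of the bivariate cosine-model von Mises density
#'
#' The joint stationary phase density of two vertically coupled rings is
#' the cosine-model bivariate von Mises distribution
#' \deqn{p(\beta_1,\beta_2) \propto \exp\{\kappa_1\cos\beta_1 +
#'   \kappa_2\cos\beta_2 + \chi\cos(\beta_1-\beta_2)\}.}
#' Its normalization has the Bessel series
#' \deqn{N = (2\pi)^2\Big[I_0(\kappa_1)I_0(\kappa_2)I_0(\chi) +
#'   2\sum_{s\ge1} I_s(\kappa_1)I_s(\kappa_2)I_s(\chi)\Big],}
#' where for \eqn{\chi < 0} the identity
#' \eqn{I_s(\chi) = (-1)^s I_s(|\chi|)} makes the terms alternate.  The
#' series is truncated adaptively (absolute term below `tol` times the
#' running sum for 3 consecutive terms) and agrees with direct 2-D
#' quadrature of the unnormalized density to near machine precision.
#'
#' @param kappa1,kappa2 stimulus concentrations (`>= 0`).
#' @param chi coupling strength (any sign).
#' @param tol relative truncation tolerance.
#' @param max_terms series cap; exceeding it raises an error.
#' @return the normalization constant `N > 0`.
#' @export
bivariate_normalization <- function(kappa1, kappa2, chi,
                                    tol = 1e-14, max_terms = 500L) {
  if (kappa1 < 0 || kappa2 < 0) stop("'kappa1' and 'kappa2' must be >= 0")
  ## work with exp-scaled Bessels: I_s(x) = e^{|x|} Is_scaled, so
  ## N = (2pi)^2 e^{kappa1 + kappa2 + |chi|} * scaled series.
  total <- bessel_signed_scaled(0, kappa1) * bessel_signed_scaled(0, kappa2) *
    bessel_signed_scaled(0, chi)
  small_run <- 0L
  for (s in seq_len(max_terms)) {
    term <- 2 * bessel_signed_scaled(s, kappa1) *
      bessel_signed_scaled(s, kappa2) * bessel_signed_scaled(s, chi)
    total <- total + term
    if (abs(term) < tol * abs(total)) {
      small_run <- small_run + 1L
      if (small_run >= 3L) {
        return((2 * pi)^2 * exp(kappa1 + kappa2 + abs(chi)) * total)
      }
    } else small_run <- 0L
  }
  stop("bivariate normalization series did not converge")
}

#' Bivariate cosine-model von Mises distribution
#'
#' @param kappa1,kappa2 stimulus concentrations (`>= 0`); when built from
#'   phase reductions these are \eqn{\kappa_j = \Lambda_j / D}.
#' @param chi coupling strength \eqn{\chi = \bar K_{eff} / D}.
#' @return an object of class `bivariate_cosine_model` with the
#'   normalization precomputed.
#' @seealso [bivariate_pdf()], [bivariate_marginal()], [modality()],
#'   [gaussian_approx()], [model_a_tuning_stats()]
#' @export
bivariate_cosine_model <- function(kappa1, kappa2, chi) {
  structure(list(kappa1 = kappa1, kappa2 = kappa2, chi = chi,
                 normalization = bivariate_normalization(kappa1, kappa2, chi)),
            class = "bivariate_cosine_model")
}

#' Joint density of the bivariate cosine model
#'
#' @param beta1,beta2 angles (vectorized together).
#' @param model a [bivariate_cosine_model()].
#' @return joint density values.
#' @export
bivariate_pdf <- function(beta1, beta2, model) {
  ## scale by the exponent's maximum to avoid overflow at large kappa
  shift <- model$kappa1 + model$kappa2 + abs(model$chi)
  exp(model$kappa1 * cos(beta1) + model$kappa2 * cos(beta2) +
        model$chi * cos(beta1 - beta2) - shift) /
    (model$normalization * exp(-shift))
}

#' Marginal phase density of the first network
#'
#' Integrating the joint density over \eqn{\beta_2} gives
#' \deqn{p(\beta_1) = N^{-1}\, 2\pi\, e^{\kappa_1\cos\beta_1}\,
#'   I_0\big(\kappa_{23}(\beta_1)\big),\quad
#'   \kappa_{23}(\beta)^2 = \kappa_2^2 + \chi^2 + 2\kappa_2\chi\cos\beta.}
#' (The composite concentration combines the stimulus drive on the
#' *other* network with the coupling; validated against direct quadrature
#' of the joint density.)  Even in \eqn{\beta_1}; reduces to the plain
#' von Mises marginal at \eqn{\chi = 0}.
#'
#' @param beta1 angle(s).
#' @param model a [bivariate_cosine_model()].
#' @return marginal density values.
#' @export
bivariate_marginal <- function(beta1, model) {
  k23 <- sqrt(model$kappa2^2 + model$chi^2 +
                2 * model$kappa2 * model$chi * cos(beta1))
  shift <- model$kappa1 + model$kappa2 + abs(model$chi)
  2 * pi * exp(model$kappa1 * cos(beta1) + k23 - shift) *
    besselI(k23, 0, expon.scaled = TRUE) / (model$normalization * exp(-shift))
}

#' Modality of the bivariate cosine model
#'
#' The joint density is unimodal iff
#' \eqn{-\chi < \kappa_1\kappa_2/(\kappa_1+\kappa_2)} and bimodal iff
#' \eqn{-\chi > \kappa_1\kappa_2/(\kappa_1+\kappa_2)} with
#' \eqn{\kappa_1,\kappa_2 > -\chi}; any \eqn{\chi \ge 0} is unimodal.
#'
#' @param kappa1,kappa2 concentrations (`> 0`).
#' @param chi coupling strength.
#' @param tol equality tolerance for the boundary case.
#' @return one of `"unimodal"`, `"bimodal"`, `"boundary"`.
#' @export
modality <- function(kappa1, kappa2, chi, tol = 1e-12) {
  if (kappa1 <= 0 || kappa2 <= 0) stop("'kappa1' and 'kappa2' must be > 0")
  h <- kappa1 * kappa2 / (kappa1 + kappa2)
  if (abs(-chi - h) <= tol) return("boundary")
  if (-chi < h) return("unimodal")
  if (kappa1 > -chi && kappa2 > -chi) "bimodal" else "unimodal"
}

#' Large-concentration Gaussian approximation
#'
#' For large \eqn{\kappa_1, \kappa_2} the phases are approximately
#' bivariate normal, \eqn{(\beta_1,\beta_2)\sim N_2(0,\Sigma)} with
#' \deqn{\Sigma^{-1} = \begin{pmatrix}\kappa_1+\chi & -\chi\\
#'   -\chi & \kappa_2+\chi\end{pmatrix},\qquad
#'   \Sigma = \frac{1}{\kappa_1\kappa_2 + \chi(\kappa_1+\kappa_2)}
#'   \begin{pmatrix}\kappa_2+\chi & \chi\\ \chi & \kappa_1+\chi\end{pmatrix}.}
#' In the symmetric case \eqn{\kappa_1=\kappa_2=\kappa} the marginal
#' variance is \eqn{(1/\kappa)(\kappa+\chi)/(\kappa+2\chi) < 1/\kappa}
#' for \eqn{\chi > 0}: vertical coupling suppresses phase fluctuations.
#'
#' @inheritParams modality
#' @return a list of class `gaussian_approx` with components `covariance`
#'   (2x2 matrix) and `precision`.
#' @export
gaussian_approx <- function(kappa1, kappa2, chi) {
  det_prec <- kappa1 * kappa2 + chi * (kappa1 + kappa2)
  if (det_prec <= 0 || kappa1 + chi <= 0)
    stop("Gaussian approximation not positive definite for these parameters")
  covariance <- matrix(c(kappa2 + chi, chi, chi, kappa1 + chi), 2, 2) / det_prec
  precision <- matrix(c(kappa1 + chi, -chi, -chi, kappa2 + chi), 2, 2)
  structure(list(covariance = covariance, precision = precision),
            class = "gaussian_approx")
}

#' Circular moments of the bivariate cosine model by 2-D quadrature
#'
#' Tensor trapezoidal rule on a periodic grid (spectrally accurate for
#' these smooth periodic integrands).  Returns the first and second
#' cosine/sine moments of each phase, the cross moments, and the linear
#' variances of the wrapped phases.
#'
#' @param model a [bivariate_cosine_model()].
#' @param n_grid grid points per dimension.
#' @return a named list of moments: `c1`, `c2` (first cosine moments),
#'   `cos2_1`, `cos2_2`, `cc` (\eqn{\langle\cos\beta_1\cos\beta_2\rangle}),
#'   `ss` (\eqn{\langle\sin\beta_1\sin\beta_2\rangle}), `var_beta1`,
#'   `var_beta2`, and `norm_quad` (quadrature check of the normalization).
#' @export
bivariate_moments <- function(model, n_grid = 361L) {
  g <- ring_grid(n_grid)
  b <- g$angles
  shift <- model$kappa1 + model$kappa2 + abs(model$chi)
  E1 <- exp(model$kappa1 * cos(b) - shift / 2)
  E2 <- exp(model$kappa2 * cos(b) - shift / 2)
  P <- outer(E1, E2) * exp(model$chi * cos(outer(b, b, "-")))
  w <- g$spacing^2
  Z <- sum(P) * w
  avg <- function(fmat) sum(fmat * P) * w / Z
  cb <- cos(b); sb <- sin(b)
  ones <- rep(1, n_grid)
  list(c1 = avg(outer(cb, ones)),
       c2 = avg(outer(ones, cb)),
       s1 = avg(outer(sb, ones)),
       cos2_1 = avg(outer(cos(2 * b), ones)),
       cos2_2 = avg(outer(ones, cos(2 * b))),
       cc = avg(outer(cb, cb)),
       ss = avg(outer(sb, sb)),
       var_beta1 = avg(outer(b^2, ones)) - avg(outer(b, ones))^2,
       var_beta2 = avg(outer(ones, b^2)) - avg(outer(ones, b))^2,
       norm_quad = Z * exp(shift))
}

#' Tuning statistics of two vertically coupled rings
#'
#' For the symmetric case \eqn{\kappa_1 = \kappa_2} computes, on a grid of
#' preference angles, the mean tuning curve
#' \eqn{\langle U_1\rangle(\theta) = A\langle\cos\beta_1\rangle\cos\theta},
#' the variance tuning curve
#' \eqn{\mathrm{var}(U_1)(\theta) = \frac{A^2}{2}[1 -
#' \langle\cos\beta_1\rangle^2 - (\langle\cos\beta_1\rangle^2 -
#' \langle\cos 2\beta_1\rangle)\cos 2\theta]}, and the equal-preference
#' cross-network correlation tuning curve, all from 2-D quadrature moments
#' of the joint density.  At \eqn{\chi = 0} the mean and variance reduce
#' exactly to the single-ring formulas and the correlation vanishes
#' identically.
#'
#' @param theta preference angle grid.
#' @param A bump amplitude.
#' @param model a [bivariate_cosine_model()] with `kappa1 == kappa2`.
#' @param n_grid quadrature resolution per dimension.
#' @return a data.frame with columns `theta`, `mean`, `variance`,
#'   `correlation`.
#' @export
model_a_tuning_stats <- function(theta, A, model, n_grid = 361L) {
  if (abs(model$kappa1 - model$kappa2) > 1e-12)
    stop("model_a_tuning_stats assumes the symmetric case kappa1 = kappa2")
  mo <- bivariate_moments(model, n_grid)
  mean_curve <- A * mo$c1 * cos(theta)
  var_curve <- (A^2 / 2) *
    (1 - mo$c1^2 - (mo$c1^2 - mo$cos2_1) * cos(2 * theta))
  cov_curve <- (A^2 / 2) * (mo$ss + mo$cc - mo$c1 * mo$c2) -
    (A^2 / 2) * (mo$ss - (mo$cc - mo$c1 * mo$c2)) * cos(2 * theta)
  corr <- cov_curve / sqrt(var_curve *
                             (A^2 / 2) * (1 - mo$c2^2 -
                                            (mo$c2^2 - mo$cos2_2) * cos(2 * theta)))
  data.frame(theta = theta, mean = mean_curve, variance = var_curve,
             correlation = corr)
}

#' Bivariate stationary density from two phase reductions
#'
#' Convenience constructor: checks the equal-diffusivity requirement
#' (`D1 = D2`, without which the stationary density has nonzero
#' probability currents and no potential form) and assembles the
#' cosine-model parameters \eqn{\kappa_j = \Lambda_j/D},
#' \eqn{\chi = \bar K_{eff}/D}.
#'
#' @param red1,red2 `phase_reduction` objects for the two networks.
#' @param tol relative tolerance on `|D1 - D2|`.
#' @return a [bivariate_cosine_model()].
#' @export
bivariate_from_reductions <- function(red1, red2, tol = 1e-8) {
  if (abs(red1$diffusion - red2$diffusion) >
      tol * max(red1$diffusion, red2$diffusion))
    stop("stationary density requires equal diffusivities D1 = D2")
  bivariate_cosine_model(red1$kappa, red2$kappa, red1$chi)
}
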