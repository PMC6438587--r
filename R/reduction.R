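#' Drift amplitude of the reduced phase equation
#'
#' For a bump pinned by a stimulus of contrast \eqn{\bar h}, the reduced
#' phase drift is \eqn{-\epsilon\Lambda\sin(\beta + \bar\theta)} with
#' \eqn{\Lambda = \bar h / A}.
#'
#' @param stim a [stimulus_params()] object.
#' @param bump a `bump_solution` with positive amplitude.
#' @return the drift amplitude \eqn{\Lambda \ge 0}.
#' @export
drift_amplitude <- function(stim, bump) {
  if (bump$amplitude <= 0) stop("no bump to pin")
  stim$contrast / bump$amplitude
}

#' Drift amplitude by adjoint projection quadrature
#'
#' Independent quadrature route to \eqn{\Lambda}: projection of the
#' stimulus onto the adjoint null vector,
#' \eqn{\Lambda = -\Gamma^{-1}\bar h \int f'(U(\theta))\sin^2\theta\,d\theta}.
#' Agrees with [drift_amplitude()]'s closed form \eqn{\bar h / A} because
#' \eqn{\Gamma = -A\int f'(U)\sin^2\theta\,d\theta}.
#'
#' @inheritParams drift_amplitude
#' @param n_points quadrature resolution.
#' @return the drift amplitude \eqn{\Lambda}.
#' @export
drift_amplitude_quadrature <- function(stim, bump, n_points = bump$n_points) {
  if (bump$amplitude <= 0) stop("no bump to pin")
  grid <- ring_grid(n_points)
  fprime <- firing_rate_deriv(bump$amplitude * cos(grid$angles), bump$params)
  s2 <- periodic_trapz(fprime * sin(grid$angles)^2, grid$spacing)
  gamma <- -bump$amplitude * s2
  -stim$contrast * s2 / gamma
}

#' Model A inter-network phase coupling function
#'
#' For the smooth interlaminar kernel \eqn{K(\theta) = E + \bar K\cos\theta}
#' the phase coupling reduces to the closed form
#' \eqn{K(\beta) = \bar K\, g(A_{other}) / A_{self}\, \sin\beta}
#' (equal to \eqn{\bar K (A_{other}/A_{self})\sin\beta} when
#' \eqn{\bar J_{other} = 1}).  The uniform component `E` is annihilated by
#' the odd adjoint null vector and contributes nothing.  The phase drift on
#' the "self" network is \eqn{-\epsilon K(\beta_{self} - \beta_{other})}.
#'
#' @param coupling a [coupling_params()] with `model = "A"`.
#' @param bump_self,bump_other `bump_solution` objects for the receiving
#'   and the sending network.
#' @return a function `K(beta)`, odd and 2*pi-periodic.
#' @export
coupling_fn_model_a <- function(coupling, bump_self, bump_other) {
  if (coupling$model != "A") stop("coupling model must be 'A'")
  if (bump_self$amplitude <= 0 || bump_other$amplitude <= 0)
    stop("both networks must carry a nonzero bump")
  amp <- coupling$modulated_amplitude *
    bump_gain(bump_other$amplitude, bump_other$params, bump_other$n_points) /
    bump_self$amplitude
  function(beta) amp * sin(beta)
}

#' Model A coupling by adjoint projection quadrature
#'
#' Independent route to the model A coupling: numerically projects the
#' coupling input \eqn{\hat K(\theta + \beta) = \int K(\theta - \theta')
#' f(U_{other}(\theta' + \beta)) d\theta'} onto the adjoint null vector.
#'
#' @inheritParams coupling_fn_model_a
#' @param beta phase lag(s) at which to evaluate.
#' @param n_points quadrature resolution.
#' @return numeric vector `K(beta)`.
#' @export
coupling_quadrature_model_a <- function(coupling, bump_self, bump_other, beta,
                                        n_points = 200L) {
  grid <- ring_grid(n_points)
  th <- grid$angles
  V <- bump_self$adjoint_null(th)
  gamma <- periodic_trapz(V * (-bump_self$amplitude * sin(th)), grid$spacing)
  f_other <- function(x) firing_rate(bump_other$amplitude * cos(x),
                                     bump_other$params)
  vapply(beta, function(b) {
    Khat <- vapply(th, function(t1) {
      periodic_trapz((coupling$uniform_component +
                        coupling$modulated_amplitude * cos(t1 - th)) *
                       f_other(th + b), grid$spacing)
    }, numeric(1))
    periodic_trapz(V * Khat, grid$spacing) / gamma
  }, numeric(1))
}

#' Model B inter-network phase coupling and potential
#'
#' For the patchy like-to-like delta kernel
#' \eqn{K(\theta) = \bar K \delta(\theta)} the phase coupling is
#' \deqn{K(\beta) = \frac{2\bar K}{\Gamma}\int_{-\pi}^{\pi}
#'   f'(U(\theta-\beta))\sin(\theta-\beta) f(U(\theta))\, d\theta,}
#' which is minus the scaled derivative of the even overlap potential
#' \eqn{\phi(\beta) = \int f(U(\theta-\beta)) f(U(\theta)) d\theta}:
#' \eqn{K(\beta) = -\frac{2\bar K}{A|\Gamma|}\phi'(\beta)}.  Both are
#' evaluated on a phase grid and returned as periodic cubic spline
#' interpolants; the two routes agree to quadrature accuracy.  The factor
#' \eqn{2/(A|\Gamma|)} absorbed into the effective coupling constant (so
#' that the stationary density carries \eqn{\chi\,\phi(\beta_1-\beta_2)}
#' with \eqn{\chi = \bar K_{eff}/D}) is recorded on the result.
#'
#' Symmetric amplitudes \eqn{A_1 = A_2} are assumed.
#'
#' @param coupling a [coupling_params()] with `model = "B"`.
#' @param bump a `bump_solution` (shared by both networks).
#' @param params a [ring_params()]; defaults to the bump's own.
#' @param n_beta number of phase-grid points on `[-pi, pi]`.
#' @param n_points ring quadrature resolution.
#' @return a list with components `K` and `phi` (functions of the phase
#'   difference), `beta` (the grid), `K_values`, `phi_values`,
#'   `prefactor` (\eqn{2/(A|\Gamma|)}) and `kbar_eff`
#'   (\eqn{2\bar K/(A|\Gamma|)}).
#' @export
coupling_fn_model_b <- function(coupling, bump, params = bump$params,
                                n_beta = 721L, n_points = 512L) {
  if (coupling$model != "B") stop("coupling model must be 'B'")
  if (bump$amplitude <= 0) stop("network must carry a nonzero bump")
  A <- bump$amplitude
  grid <- ring_grid(n_points)
  th <- grid$angles
  f_th <- firing_rate(A * cos(th), params)
  fprime <- function(x) firing_rate_deriv(A * cos(x), params)
  gamma <- -A * periodic_trapz(fprime(th) * sin(th)^2, grid$spacing)

  beta <- seq(-pi, pi, length.out = n_beta)
  kbar <- coupling$modulated_amplitude
  K_values <- vapply(beta, function(b) {
    (2 * kbar / gamma) *
      periodic_trapz(fprime(th - b) * sin(th - b) * f_th, grid$spacing)
  }, numeric(1))
  phi_values <- vapply(beta, function(b) {
    periodic_trapz(firing_rate(A * cos(th - b), params) * f_th, grid$spacing)
  }, numeric(1))
  ## enforce exact periodicity at the seam for the periodic splines
  K_values[n_beta] <- K_values[1]
  phi_values[n_beta] <- phi_values[1]
  list(K = splinefun(beta, K_values, method = "periodic"),
       phi = splinefun(beta, phi_values, method = "periodic"),
       beta = beta, K_values = K_values, phi_values = phi_values,
       prefactor = 2 / (A * abs(gamma)),
       kbar_eff = 2 * kbar / (A * abs(gamma)))
}

#' Phase diffusion coefficient
#'
#' Projects the spatially structured noise onto the translation mode:
#' \deqn{D = \Gamma^{-2}\int\!\!\int V(\theta)V(\theta')
#'   C(\theta-\theta')\,d\theta\,d\theta',\qquad
#'   V(\theta) = f'(U(\theta))\sin\theta.}
#' By linearity in the correlation function
#' \eqn{C(\theta) = a\delta(\theta) + b\cos\theta},
#' `D = a * D_white + b * D_cos` with
#' \eqn{D_{white} = \Gamma^{-2}\int \sin^2\theta\,[f'(U)]^2 d\theta} and
#' \eqn{D_{cos} = \Gamma^{-2}[\int f'(U)\sin^2\theta\, d\theta]^2 = 1/A^2}
#' (the last equality holds at an exact bump root, where
#' \eqn{\int f'(U)\sin^2 = 1/\bar J} and \eqn{\Gamma = -A/\bar J}).
#' Spatially homogeneous noise (constant `C`) contributes zero because
#' \eqn{f'(U)} is even.
#'
#' @param noise a [noise_params()] object (fields `white_weight` = a,
#'   `cosine_weight` = b).  Ignored when `correlation` is supplied.
#' @param bump a `bump_solution` with positive amplitude.
#' @param params a [ring_params()]; defaults to the bump's own.
#' @param n_points quadrature resolution.
#' @param correlation optional smooth correlation function `C(theta)`;
#'   if supplied, `D` is computed by direct double quadrature of the
#'   general quadratic form instead of the `a`/`b` decomposition.
#' @return the diffusion coefficient `D >= 0`.
#' @export
diffusion_coefficient <- function(noise, bump, params = bump$params,
                                  n_points = 512L, correlation = NULL) {
  if (bump$amplitude <= 0) stop("diffusion requires a nonzero bump")
  grid <- ring_grid(n_points)
  th <- grid$angles
  V <- firing_rate_deriv(bump$amplitude * cos(th), params) * sin(th)
  gamma <- -bump$amplitude *
    periodic_trapz(firing_rate_deriv(bump$amplitude * cos(th), params) *
                     sin(th)^2, grid$spacing)
  if (!is.null(correlation)) {
    d <- outer(th, th, "-")
    Cmat <- matrix(rep_len(correlation(as.vector(d)), length(d)),
                   nrow = nrow(d))   # tolerate constant correlations
    return(drop(t(V) %*% Cmat %*% V) * grid$spacing^2 / gamma^2)
  }
  d_white <- periodic_trapz((V)^2, grid$spacing) / gamma^2
  s2 <- periodic_trapz(V * sin(th), grid$spacing)
  d_cos <- s2^2 / gamma^2
  noise$white_weight * d_white + noise$cosine_weight * d_cos
}

#' Construct a phase reduction from explicit coefficients
#'
#' Direct constructor for a reduced phase process with drift amplitude
#' \eqn{\Lambda}, diffusion coefficient `D` and weak-coupling scale
#' \eqn{\epsilon} (stationary concentration
#' \eqn{\kappa = \Lambda/(\epsilon D)}).  [build_phase_reduction()]
#' computes these from a network configuration; this constructor is for
#' studying the reduced process in its own right, where only the
#' dimensionless combinations matter.
#'
#' @param drift_amplitude \eqn{\Lambda \ge 0}.
#' @param diffusion \eqn{D > 0}.
#' @param epsilon weak-coupling scale in (0, 1].
#' @param stimulus optional [stimulus_params()] carried for the bias.
#' @return a `phase_reduction` with no inter-network coupling.
#' @export
phase_reduction <- function(drift_amplitude, diffusion, epsilon = 0.05,
                            stimulus = NULL) {
  if (drift_amplitude < 0 || diffusion <= 0 || epsilon <= 0 || epsilon > 1)
    stop("invalid phase-reduction coefficients")
  new_phase_reduction(drift_amplitude, diffusion, epsilon, "none",
                      stimulus = stimulus)
}

new_phase_reduction <- function(Lambda, D, epsilon, coupling_model,
                                K = NULL, phi = NULL, kbar_eff = 0,
                                bump = NULL, stimulus = NULL) {
  structure(list(drift_amplitude = Lambda,
                 diffusion = D,
                 epsilon = epsilon,
                 coupling_model = coupling_model,
                 coupling_fn = if (is.null(K)) function(beta) 0 * beta else K,
                 potential_phi = phi,
                 kbar_eff = kbar_eff,
                 kappa = if (D > 0) Lambda / (epsilon * D) else Inf,
                 chi = if (D > 0) kbar_eff / (epsilon * D) else 0,
                 amplitude = if (is.null(bump)) NA_real_ else bump$amplitude,
                 bump = bump,
                 stimulus = stimulus),
            class = "phase_reduction")
}

#' @export
print.phase_reduction <- function(x, ...) {
  cat(sprintf(
    "phase_reduction: Lambda = %.5f, D = %.5f, model = %s, kappa = %.4f, chi = %.4f\n",
    x$drift_amplitude, x$diffusion, x$coupling_model, x$kappa, x$chi))
  invisible(x)
}

#' Build the reduced stochastic phase description
#'
#' Packages the drift amplitude \eqn{\Lambda = \bar h/A}, the diffusion
#' coefficient `D`, and (for two networks) the coupling function `K` into
#' one `phase_reduction` per network, with the sign convention
#' \deqn{d\beta_j = -\epsilon\Lambda_j\sin(\beta_j + \bar\theta_j)\,dt
#'   - \epsilon K_j(\beta_j - \beta_{other})\,dt
#'   + \sqrt{2 D_j}\,\epsilon\, dw_j.}
#' `K` is odd with `K'(0) > 0` for excitatory coupling, so excitatory
#' coupling attracts the two phases.  Drift, coupling and noise are all
#' of order \eqn{\epsilon} (matching the field equations, where stimulus,
#' coupling and noise all carry the same weak scale), so the phase
#' diffusion coefficient is \eqn{\epsilon^2 D} and the stationary
#' concentration is \eqn{\kappa = \Lambda/(\epsilon D) = \bar h/(\epsilon A D)};
#' the stationary coupling strength is \eqn{\chi = \bar K_{eff}/(\epsilon D)}.
#' Both are stored on the result.
#'
#' @param rings one [ring_params()] or a list of two.
#' @param stimuli one [stimulus_params()] or a list of two.
#' @param noise a [noise_params()] (shared) or list of two.
#' @param coupling a [coupling_params()]; `model = "none"` (default) for
#'   uncoupled/single networks.
#' @param bumps optional pre-solved stable `bump_solution`s (recomputed
#'   from `rings` otherwise).
#' @param n_points quadrature resolution.
#' @return a `phase_reduction` for a single network, or an unnamed list of
#'   two for a coupled pair.
#' @examples
#' red <- build_phase_reduction(ring_params(1, 4, 0.5),
#'                              stimulus_params(contrast = 2),
#'                              noise_params(0.05, 3, 0.5))
#' red$kappa   # stationary von Mises concentration Lambda / D
#' @export
build_phase_reduction <- function(rings, stimuli, noise,
                                  coupling = coupling_params("none"),
                                  bumps = NULL, n_points = 200L) {
  single <- inherits(rings, "ring_params")
  ring_list <- if (single) list(rings) else rings
  stim_list <- if (inherits(stimuli, "stimulus_params")) list(stimuli) else stimuli
  noise_list <- if (inherits(noise, "noise_params")) list(noise) else noise
  m <- length(ring_list)
  if (m > 2L) stop("at most two coupled networks are supported")
  if (length(stim_list) == 1L) stim_list <- rep(stim_list, m)
  if (length(noise_list) == 1L) noise_list <- rep(noise_list, m)

  if (is.null(bumps)) {
    bumps <- lapply(ring_list, function(rp) {
      sols <- solve_bump(rp, n_points = n_points)
      stable <- Filter(function(b) b$amplitude > 0 && b$is_stable, sols)
      if (length(stable) == 0L)
        stop("no stable nonzero bump: cannot build a phase reduction")
      stable[[length(stable)]]
    })
  } else if (inherits(bumps, "bump_solution")) bumps <- list(bumps)

  reds <- vector("list", m)
  for (j in seq_len(m)) {
    other <- if (m == 2L) 3L - j else j
    Lambda <- drift_amplitude(stim_list[[j]], bumps[[j]])
    D <- diffusion_coefficient(noise_list[[j]], bumps[[j]], ring_list[[j]])
    K <- NULL; phi <- NULL; kbar_eff <- 0
    if (coupling$model == "A" && m == 2L) {
      K <- coupling_fn_model_a(coupling, bumps[[j]], bumps[[other]])
      kbar_eff <- coupling$modulated_amplitude *
        bump_gain(bumps[[other]]$amplitude, ring_list[[other]], n_points) /
        bumps[[j]]$amplitude
    } else if (coupling$model == "B") {
      cb <- coupling_fn_model_b(coupling, bumps[[j]], ring_list[[j]])
      K <- cb$K; phi <- cb$phi; kbar_eff <- cb$kbar_eff
    }
    reds[[j]] <- new_phase_reduction(Lambda, D, noise_list[[j]]$epsilon,
                                     coupling$model, K, phi, kbar_eff,
                                     bumps[[j]], stim_list[[j]])
  }
  if (single) reds[[1]] else reds
}

#' Serialize a phase reduction
#'
#' Scalar coefficients as a JSON string, with the coupling function and
#' potential sampled on a phase grid as parallel columns.
#'
#' @param reduction a `phase_reduction`.
#' @param n_beta number of sample points for `K` and `phi`.
#' @return a JSON string.
#' @export
reduction_to_json <- function(reduction, n_beta = 181L) {
  beta <- seq(-pi, pi, length.out = n_beta)
  obj <- list(drift_amplitude = reduction$drift_amplitude,
              diffusion = reduction$diffusion,
              epsilon = reduction$epsilon,
              kappa = reduction$kappa,
              chi = reduction$chi,
              coupling_model = reduction$coupling_model,
              amplitude = reduction$amplitude,
              samples = data.frame(
                beta = beta,
                K = reduction$coupling_fn(beta),
                phi = if (is.null(reduction$potential_phi)) rep(NA_real_, n_beta)
                      else reduction$potential_phi(beta)))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}
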