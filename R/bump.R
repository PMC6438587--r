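#' Sigmoidal firing-rate function
#'
#' \eqn{f(u) = f_0 / (1 + e^{-\gamma(u - \eta)})}: strictly increasing,
#' bounded in \eqn{(0, f_0)}.
#'
#' @param u activity value(s).
#' @param params a [ring_params()] object.
#' @return firing rate(s), same shape as `u`.
#' @export
firing_rate <- function(u, params) {
  params$max_rate * plogis(params$gain * (u - params$threshold))
}

#' Derivative of the firing-rate function
#'
#' \eqn{f'(u) = \gamma f(u) (1 - f(u)/f_0)}, evaluated in an
#' overflow-safe way.
#'
#' @inheritParams firing_rate
#' @return `f'(u)`, same shape as `u`.
#' @export
firing_rate_deriv <- function(u, params) {
  params$max_rate * params$gain * dlogis(params$gain * (u - params$threshold))
}

#' Bump gain function g(A)
#'
#' First cosine moment of the firing rate of a cosine bump,
#' \eqn{g(A) = \int_{-\pi}^{\pi} \cos\theta\, f(A\cos\theta)\, d\theta},
#' evaluated by periodic trapezoidal quadrature.  Stationary bump
#' amplitudes solve \eqn{A = \bar J g(A)}.  `g` is odd in `A` and
#' `g(0) = 0`.
#'
#' @param A bump amplitude(s).
#' @param params a [ring_params()] object.
#' @param n_points quadrature resolution.
#' @return `g(A)`, same shape as `A`.
#' @export
bump_gain <- function(A, params, n_points = 200L) {
  grid <- ring_grid(n_points)
  vapply(A, function(a) {
    periodic_trapz(cos(grid$angles) * firing_rate(a * cos(grid$angles), params),
                   grid$spacing)
  }, numeric(1))
}

## Stability classification with a marginal band around lambda_e = 0.
classify_stability <- function(lambda_even, tol = 1e-8) {
  if (abs(lambda_even) <= tol) "marginal-even"
  else if (lambda_even < 0) "stable"
  else "unstable"
}

new_bump_solution <- function(amplitude, params, n_points, residual = 0) {
  A <- amplitude
  profile <- function(theta) A * cos(theta)
  adjoint_null <- function(theta) {
    firing_rate_deriv(A * cos(theta), params) * sin(theta)
  }
  grid <- ring_grid(n_points)
  fprime <- firing_rate_deriv(A * cos(grid$angles), params)
  if (A > 0) {
    ## Gamma = int V(theta) U'(theta) dtheta = -A int f'(U) sin^2  (< 0);
    ## at an exact root this equals -A / Jbar.
    gamma_norm <- -A * periodic_trapz(fprime * sin(grid$angles)^2, grid$spacing)
    lambda_even <- 2 * (params$weight_amplitude *
                          periodic_trapz(fprime, grid$spacing) / 2 - 1)
  } else {
    ## Zero state: the linearization about u = 0 has eigenvalue
    ## pi * Jbar * f'(0) - 1 for both the cos and sin modes.
    gamma_norm <- NA_real_
    lambda_even <- pi * params$weight_amplitude *
      firing_rate_deriv(0, params) - 1
  }
  stability <- classify_stability(lambda_even)
  structure(list(amplitude = A,
                 profile = profile,
                 adjoint_null = adjoint_null,
                 gamma_norm = gamma_norm,
                 lambda_zero = if (A > 0) 0 else NA_real_,
                 lambda_even = lambda_even,
                 stability = stability,
                 is_stable = identical(stability, "stable"),
                 residual = residual,
                 n_points = n_points,
                 params = params),
            class = "bump_solution")
}

#' @export
print.bump_solution <- function(x, ...) {
  cat(sprintf("bump_solution: A = %.6f (%s), lambda_0 = %s, lambda_e = %.6f\n",
              x$amplitude, x$stability,
              if (is.na(x$lambda_zero)) "NA" else format(x$lambda_zero),
              x$lambda_even))
  invisible(x)
}

#' Solve for stationary bump amplitudes
#'
#' Finds all stationary bump solutions \eqn{U(\theta) = A\cos\theta} of a
#' single homogeneous ring by locating the roots of
#' \eqn{r(A) = A - \bar J g(A)} with a uniform bracketing scan on
#' `(0, scan_max]` followed by Brent refinement, plus the trivial `A = 0`
#' state (flagged with `amplitude = 0`).  Each root carries its stability
#' classification from the translation (\eqn{\lambda_0 = 0}) and
#' even/amplitude (\eqn{\lambda_e}) eigenvalues.
#'
#' @param params a [ring_params()] object.
#' @param tol refinement tolerance on `|A - Jbar g(A)|`.
#' @param scan_max upper end of the bracketing scan.
#' @param n_points quadrature resolution for `g`.
#' @param n_brackets number of uniform scan brackets.
#' @return a list of `bump_solution` objects, zero state first, nonzero
#'   roots in increasing amplitude.  Warns `"no nonzero bump"` when the
#'   scan finds no sign change (e.g. `Jbar` too small).
#' @examples
#' sols <- solve_bump(ring_params(1, 4, 0.5))
#' sols[[2]]$amplitude   # ~ 1.85, the stable bump
#' @export
solve_bump <- function(params, tol = 1e-10, scan_max = 10,
                       n_points = 200L, n_brackets = 400L) {
  if (scan_max <= 0) stop("'scan_max' must be > 0")
  res_fun <- function(A) A - params$weight_amplitude *
    bump_gain(A, params, n_points)
  out <- list(new_bump_solution(0, params, n_points))
  if (params$weight_amplitude == 0) return(out)

  a_grid <- seq(scan_max / n_brackets, scan_max, length.out = n_brackets)
  r_grid <- vapply(a_grid, res_fun, numeric(1))
  flips <- which(r_grid[-1] * r_grid[-n_brackets] <= 0 &
                   !(r_grid[-1] == 0 & r_grid[-n_brackets] == 0))
  roots <- numeric(0)
  for (i in flips) {
    root <- uniroot(res_fun, lower = a_grid[i], upper = a_grid[i + 1],
                    tol = tol / 10)$root
    if (abs(res_fun(root)) < max(tol, 1e-12)) roots <- c(roots, root)
  }
  roots <- sort(roots)
  if (length(roots) > 1) {       # merge duplicates
    keep <- c(TRUE, diff(roots) > 1e-6)
    roots <- roots[keep]
  }
  roots <- roots[roots > 1e-8]
  if (length(roots) == 0L) {
    warning("no nonzero bump: no sign change of A - Jbar g(A) on (0, scan_max]")
    return(out)
  }
  c(out, lapply(roots, function(r) {
    new_bump_solution(r, params, n_points, residual = abs(res_fun(r)))
  }))
}

#' Bump linear-stability eigenvalues
#'
#' The linearization of the ring dynamics about a bump has two
#' non-essential eigenvalues: \eqn{\lambda_0 = 0} (uniform translations of
#' the bump; marginal stability, generator \eqn{\sin\theta}) and
#' \eqn{\lambda_e = 2[\bar J \int_0^\pi f'(U(\theta))d\theta - 1]}
#' (amplitude expansion/contraction, generator \eqn{\cos\theta}).
#' \eqn{\lambda_0} is returned as exact 0 by construction;
#' \eqn{\lambda_e} is evaluated by quadrature.
#'
#' @param bump a `bump_solution` with positive amplitude.
#' @param params a [ring_params()] object; defaults to the bump's own.
#' @param n_points quadrature resolution.
#' @return named numeric vector `c(lambda_zero = 0, lambda_even = ...)`.
#' @export
stability_eigenvalues <- function(bump, params = bump$params,
                                  n_points = bump$n_points) {
  if (bump$amplitude <= 0)
    stop("stability_eigenvalues requires a nonzero bump")
  grid <- ring_grid(n_points)
  fprime <- firing_rate_deriv(bump$amplitude * cos(grid$angles), params)
  ## f'(U(theta)) is even and periodic, so int_0^pi = (1/2) int_{-pi}^{pi},
  ## and the periodic trapezoid rule is spectrally accurate.
  lambda_even <- 2 * (params$weight_amplitude *
                        periodic_trapz(fprime, grid$spacing) / 2 - 1)
  c(lambda_zero = 0, lambda_even = lambda_even)
}

#' Discretized bump linearization operator
#'
#' Matrix `M` approximating the linear operator
#' \eqn{\psi \mapsto -\psi + J * (f'(U)\psi)} on the ring grid via
#' trapezoidal weights, so that the eigenproblem
#' \eqn{(\lambda + 1)\psi = \int J(\theta-\theta')f'(U(\theta'))\psi(\theta')d\theta'}
#' becomes `M psi = lambda psi`.  Its two leading eigenvalues approximate
#' \eqn{(\lambda_0, \lambda_e)}; the remaining `n_points - 2` eigenvalues
#' equal \eqn{-1} (the essential spectrum).
#'
#' @param bump a `bump_solution`.
#' @param params a [ring_params()] object; defaults to the bump's own.
#' @param grid a [ring_grid()].
#' @return an `n_points` by `n_points` numeric matrix.
#' @export
discretized_linear_operator <- function(bump, params = bump$params,
                                        grid = ring_grid(bump$n_points)) {
  th <- grid$angles
  fprime <- firing_rate_deriv(bump$amplitude * cos(th), params)
  J <- params$weight_amplitude * cos(outer(th, th, "-"))
  -diag(grid$n_points) + J %*% diag(fprime) * grid$spacing
}
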