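---
title: "Stochastic wandering bumps on the ring: model, reduction, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic wandering bumps on the ring: model, reduction, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringwander)
```

## The model

`ringwander` studies trial-to-trial variability of population tuning
curves in ring attractor networks.  A ring network is a continuum of
rate units labeled by a preferred direction $\theta \in [-\pi,\pi)$,
with first-harmonic recurrent weights $J(\theta) = \bar J\cos\theta$
(like-to-like excitation, cross-direction inhibition) and a sigmoidal
population rate $f(u) = f_0/(1+e^{-\gamma(u-\eta)})$.  One or two such
rings evolve as stochastic neural fields

$$
du_j = \Big[-u_j + J * f(u_j) + \epsilon K * f(u_{3-j})
      + \epsilon \bar h_j \cos(\theta - \bar\theta_j)\Big]\,dt
      + \sqrt{2}\,\epsilon\, dW_j ,
$$

where time is measured in units of the membrane time constant $\tau$
(10 ms by default, used only to label outputs), $*$ denotes ring
convolution, and the noise is white in time with spatial correlation
$C(\theta) = a\,\delta(\theta) + b\cos\theta$.  The scale factor
$\epsilon \ll 1$ makes stimulus, inter-network coupling and noise
jointly weak, which is what licenses the perturbative reduction below.

Two coupled architectures are supported.  **Model A** ("vertical",
two cortical layers of one hypercolumn):
$K(\theta) = E + \bar K\cos\theta$.  **Model B** ("horizontal", two
hypercolumns linked by patchy like-to-like connections):
$K(\theta) = \bar K\,\delta(\theta)$, applied pointwise (the exact
action of a Dirac delta under the integral — no grid-spacing factor).

Without stimulus, coupling or noise, each ring supports a stationary
bump $U(\theta) = A\cos\theta$ with $A$ solving $A = \bar J g(A)$,
$g(A) = \int\cos\theta\, f(A\cos\theta)\,d\theta$
(`solve_bump()`; at $\bar J = 1,\ \gamma = 4,\ \eta = 0.5,\ f_0 = 1$
the stable root is $A \approx 1.85$).  The linearization has eigenvalue
$\lambda_0 = 0$ (rotations — the bump is marginally stable, its
position free) and
$\lambda_e = 2[\bar J\int_0^\pi f'(U) - 1]$ (amplitude mode); all other
eigenvalues sit at $-1$ (essential spectrum).  `ringwander` computes
$\lambda_e$ both by quadrature and from the eigenvalues of the
discretized operator (`discretized_linear_operator()`), and the two
routes are cross-checked in the test suite.

A note on $f_0$: the printed worked amplitude $A \approx 1.85$ is only
consistent with the dimensionless rate $f_0 = 1$.  A physical maximal
rate (e.g. 100 spikes/s) is treated purely as a display scaling and
never enters the fixed-point solve.

## The phase reduction

Marginal stability means noise makes the bump *wander*: its phase
$\beta(t)$ (center of mass) diffuses along the ring.  Projecting the
field fluctuations onto the rotation mode — the adjoint null vector is
$V(\theta) = f'(U(\theta))\sin\theta$ — yields coupled phase SDEs

$$
d\beta_j = -\epsilon\Lambda_j \sin(\beta_j + \bar\theta_j)\,dt
         \;-\; \epsilon K_j(\beta_j - \beta_{3-j})\,dt
         \;+\; \epsilon\sqrt{2D_j}\,dw_j ,
$$

with drift amplitude $\Lambda_j = \bar h_j/A_j$, diffusion coefficient
$D_j = \Gamma_j^{-2}\iint V V' C$ (for the standard correlation,
$D = a\,\Gamma^{-2}\!\int \sin^2\theta\,[f'(U)]^2 + b/A^2$), and
normalization $\Gamma_j = -A_j/\bar J_j$.  For model A the coupling has
the closed form $K(\beta) = \bar K (A_{other}/A_{self})\sin\beta$ (the
uniform kernel component $E$ is annihilated by the odd $V$); for model
B it is the scaled derivative of the even overlap potential
$\phi(\beta) = \int f(U(\theta-\beta)) f(U(\theta))\,d\theta$:
$K(\beta) = -\tfrac{2\bar K}{A|\Gamma|}\phi'(\beta)$.  Both routes are
computed and compared in `coupling_fn_model_b()`.

Sign conventions are standardized so that $K$ is odd with $K'(0) > 0$
for excitatory coupling, making excitatory coupling *attract* the two
phases (the drift on the phase difference is $-2\epsilon K(\beta_1 -
\beta_2)$); the model's various equivalent display forms differ only by
which argument order and absorbed constants they use, and the package
records the model-B absorbed constant $2/(A|\Gamma|)$ on the returned
object so either display is recoverable.

### Noise scaling — the one genuinely open convention

The weak-noise term can be typeset ambiguously as either
$\sqrt{2\epsilon}\,dW$ or $\sqrt2\,\epsilon\,dW$.  The package uses
$\sqrt2\,\epsilon\,dW$, for two reasons that the test suite makes
measurable:

1. Only this scaling reproduces the closed-form steady-state
   concentrations $\kappa = \bar h/(\epsilon A D)$ and
   $\chi = \bar K_{\rm eff}/(\epsilon D)$ that all the analytic
   statistics (and the package's figures-level experiments) are built
   on.
2. Under the alternative $\sqrt{2\epsilon}$ scaling, the standard
   illustration parameters ($\epsilon = 0.05$, $a = 3$,
   $\Delta\theta = 0.01\pi$) give a pointwise white-noise standard
   deviation of $\approx 2.2$ — larger than the bump amplitude — and
   the bump collapses within tens of $\tau$, contradicting the regime
   the model is meant to illustrate.  Under the adopted scaling the
   pointwise noise sd is $\approx 0.49$ and the bump persists.

Consequently the phase diffusion coefficient is $\epsilon^2 D$: the
variance of the unwrapped free phase grows as $2\epsilon^2 D\,t$, and
mixing to the uniform density from a point takes $O(1/(\epsilon^2 D))
\approx 3000\tau$ at the default parameters.  Tests that probe the
$\bar h = 0$ stationary density therefore initialize realizations from
the uniform law (testing stationarity) rather than waiting out the
mixing time.

## Steady-state circular statistics

For a single ring the stationary phase density is von Mises,
$M(\beta;0,\kappa) \propto e^{\kappa\cos\beta}$ with
$\kappa = \bar h/(\epsilon A D)$ — uniform without a stimulus,
sharply peaked (Gaussian with $\sigma^2 = 1/\kappa$) at high contrast.
Averaging the rigidly wandering bump $A\cos(\theta+\beta)$ over this
law gives the mean tuning curve $A\,\frac{I_1}{I_0}(\kappa)\cos\theta$
and the variance tuning curve

$$
\mathrm{var}(U)(\theta) = \frac{A^2}{2}\Big[1 - r_1^2 -
  (r_1^2 - r_2)\cos 2\theta\Big],\qquad r_n = I_n(\kappa)/I_0(\kappa),
$$

which is flat at $A^2/2$ for $\kappa = 0$ and *M-shaped* for
$\kappa > 0$: variance minima at the stimulus direction, maxima
flanking it at $\pm\pi/2$.  This is the model's simple account of the
experimentally observed bimodal tuning of response variability.
`firing_rate_variance()` provides the same statistic for $f(u)$ by
quadrature.

For model A the joint stationary phase density is the **cosine-model
bivariate von Mises**
$\propto \exp(\kappa_1\cos\beta_1 + \kappa_2\cos\beta_2 +
\chi\cos(\beta_1 - \beta_2))$.  Its normalization is evaluated by the
Bessel product series
$N = (2\pi)^2[I_0 I_0 I_0(\chi) + 2\sum_{s\ge1} I_s(\kappa_1)
I_s(\kappa_2) I_s(\chi)]$ with $I_s(\chi) = (-1)^s I_s(|\chi|)$ for
$\chi < 0$ — this is the form that agrees with direct 2-D quadrature of
the density to machine precision for *both* signs of $\chi$ (an
alternating-sign series sometimes quoted for this model belongs to the
convention with a $-\chi\cos(\beta_1-\beta_2)$ interaction term, and
does not).  Marginals, modality (unimodal iff
$-\chi < \kappa_1\kappa_2/(\kappa_1+\kappa_2)$), the
large-$\kappa$ bivariate-normal limit with
$\Sigma^{-1} = \binom{\kappa_1+\chi\;\; -\chi}{-\chi\;\;
\kappa_2+\chi}$, and the mean/variance/correlation tuning curves all
follow; positive $\chi$ (excitatory vertical coupling) suppresses phase
variance, $\mathrm{var}(\beta) = \kappa^{-1}(\kappa+\chi)/(\kappa+2\chi)
< \kappa^{-1}$, and induces an interlaminar correlation tuning curve
that vanishes identically at $\chi = 0$.

In the derived marginal density the composite concentration
$\sqrt{\kappa_2^2 + \chi^2 + 2\kappa_2\chi\cos\beta_1}$ combines the
*other* network's stimulus drive with the coupling; a printed form that
swaps the two stimulus indices appears in the literature, so
`bivariate_marginal()` is defined by direct integration of the joint
density and validated against 2-D quadrature rather than against any
printed display.

For model B the stationary density generalizes to
$\propto \exp\{\kappa\cos(\beta_1+\bar\theta_1) +
\kappa\cos(\beta_2+\bar\theta_2) + \chi\,\phi(\beta_1-\beta_2)\}$ with
the tabulated overlap potential $\phi$; the normalization has no closed
form and is always numerical.  `model_b_center_stats()` sweeps the
surround bias and reports the center network's peak normalized mean and
maximal normalized variance.  Because a nonzero surround bias breaks
the evenness of the joint density, the first and second *sine* moments
of $\beta_1$ need not vanish; the package therefore assembles the exact
mean and variance from all four first/second harmonic moments (this
reduces to the cosine-only textbook display in the symmetric cases
$\bar\theta = 0, \pi$).  The characteristic predictions: with net
inhibitory horizontal coupling ($\chi<0$) center variance is
*facilitated* when center and surround biases agree and suppressed when
they oppose; the reverse for $\chi>0$; and mean and variance always
move in opposite directions.

## Numerics

* **Quadrature.** All ring integrals use the composite trapezoidal rule
  on the periodic grid (spectrally accurate for smooth periodic
  integrands); default $\Delta\theta = 0.01\pi$ ($n = 200$), matching
  the stated numerical scheme.  2-D densities use the tensor rule on a
  $361^2$ grid (241 for model-B sweeps), with doubled-resolution checks
  in the tests.
* **Root finding.** `solve_bump()` scans 400 uniform brackets on
  $(0, 10]$ and refines sign changes with Brent's method to $10^{-10}$,
  merging duplicates closer than $10^{-6}$.  $|\lambda_e| \le 10^{-8}$
  is classified "marginal-even", not stable.
* **Bessel evaluation.** Exponentially scaled `besselI` throughout, so
  ratios and the normalization series stay finite for large
  concentrations; the series truncates when three consecutive terms
  fall below $10^{-14}$ of the running sum (cap 500 — never reached for
  finite arguments).
* **Integration.** Euler–Maruyama, forward Euler in time and trapezoid
  in $\theta$, default $\Delta t = 10^{-3}\tau$.  The cosine noise
  component is sampled exactly through its rank-2 decomposition
  ($\xi_1\cos\theta + \xi_2\sin\theta$); the delta component as
  independent normals of variance $a\,dt/\Delta\theta$ per grid point.
  The integrators (C++) use a seeded xoshiro256++ generator with a
  ziggurat normal sampler — R's inversion sampler would dominate the
  run time — so trajectories are bitwise-reproducible given a seed,
  with per-trajectory seeds derived from a master seed by a counter
  (`seed + k`).
* **Phase extraction.** $\hat\beta = -\arg\sum_i u(\theta_i)
  e^{i\theta_i}\Delta\theta$, exact for first-harmonic fields and
  orthogonal to even-harmonic contamination; an error is raised when
  the first-harmonic amplitude falls below $10^{-8}$ ("no bump").
* **Model-B coupling cache.** $K$ and $\phi$ are tabulated on 721
  equispaced phase points and wrapped in periodic cubic splines; the
  SDE integrator resamples $K$ onto a 4096-point table with linear
  interpolation (error far below the Euler–Maruyama discretization
  error).
* **Equal diffusivities.** The stationary densities exist as
  zero-current solutions only when $D_1 = D_2$;
  `bivariate_from_reductions()` enforces this and errors otherwise.

## What a green simulation test does and does not establish

The simulators and the analytics validate each other at three levels:
free diffusion (variance slope $2\epsilon^2 D$, recovered within a few
percent), stationary histograms of the reduced SDE against the von
Mises/cosine-model densities (total-variation distance $< 0.03$ at the
tested sample sizes), and full-field histograms against the reduction.
The last is the demanding one: the reduction is *leading order in*
$\epsilon$.  At the default illustration parameters ($\epsilon = 0.05$,
$a = 3$) the pointwise noise sd (0.49) is comparable to the sigmoid
width ($1/\gamma = 0.25$), and the stimulus-locked field is measurably
*more* concentrated than the analytic prediction (fitted concentration
$\approx 37$ against the predicted $29$): the restoring rate exceeds
$\epsilon\Lambda$ by roughly 20% because the stimulus also deforms the
bump ($A_{\rm eff}$ solving $A = \bar J g(A) + \epsilon\bar h$), and
the effective diffusion is correspondingly reduced.  At the tested
ensemble size this bias consumes most of the stated total-variation
tolerance (measured TV $\approx 0.06$ of an allowed $0.08$); a
matched-$\kappa$ run at $\epsilon = 0.025$ brings the fitted
concentration to within 5% of the prediction, demonstrating convergence
to the reduction as $\epsilon \to 0$.  Green simulation tests therefore
establish *consistency of the implementation with the theory in the
theory's own regime*; at the illustration noise level the leading-order
theory is only accurate to within these documented corrections.

The synthetic worlds simulated here are rigid-bump worlds: all
variability enters through the phase (and, in the full field, through
transverse fluctuations around the bump).  Real cortical data add
amplitude fluctuations, spiking noise, adaptation, and heterogeneity
that the model deliberately omits; none of the tests bear on those.

## Defaults

| Parameter | Default | Meaning |
|---|---|---|
| $\bar J$ | 1 | recurrent weight amplitude |
| $\gamma$, $\eta$, $f_0$ | 4, 0.5, 1 | sigmoid gain, threshold, max rate (dimensionless) |
| $\tau$ | 10 ms | time constant (display only; integration in units of $\tau$) |
| $\epsilon$ | 0.05 | weak stimulus/coupling/noise scale |
| $a$, $b$ | 3, 0.5 | white and cosine noise weights |
| $\Delta t$, $\Delta\theta$ | $10^{-3}$, $0.01\pi$ | integration steps |
| $\kappa$ grid (model B) | 1 | surround-sweep stimulus concentration |

These are the standard illustration values; experiments accept
overrides through `experiment_config()` and the JSON config files of
the CLI (`exec/ringwander`).  YAML configs are not supported (no YAML
parser among the package's dependencies); JSON carries the same schema.
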