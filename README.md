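# ringwander

Stochastic wandering bumps and stimulus-dependent variability in ring
attractor networks.

## The problem

Cortical responses are variable from trial to trial, and that
variability is itself *tuned*: presenting a stimulus suppresses it, and
the suppression is strongest at the preferred direction, leaving an
M-shaped (bimodal) variance tuning curve with maxima flanking the
stimulus.  A parsimonious dynamical account models a population of
direction-selective neurons as a **ring attractor**: a neural field
$u(\theta,t)$ on $\theta \in [-\pi,\pi)$ with cosine recurrent weights
$\bar J\cos\theta$ and sigmoidal rate
$f(u) = f_0/(1+e^{-\gamma(u-\eta)})$ supports a stationary activity
bump $U(\theta) = A\cos\theta$ — the population tuning curve — that is
*marginally stable*: its position is free, so weak noise makes it
wander, and a weak stimulus $\epsilon\bar h\cos(\theta-\bar\theta)$
pins it.

`ringwander` implements this program end to end, for one ring and for
two coupled rings (vertically coupled cortical layers, "model A", or
horizontally coupled hypercolumns, "model B"):

* **Bumps and stability** — solve $A = \bar J\int\cos\theta\,
  f(A\cos\theta)\,d\theta$, eigenvalues $\lambda_0 = 0$,
  $\lambda_e = 2[\bar J\int_0^\pi f'(U)-1]$, and the discretized
  linearization operator.
* **Phase reduction** — project the stochastic field onto the rotation
  mode to get $d\beta = -\epsilon\Lambda\sin(\beta+\bar\theta)\,dt -
  \epsilon K(\beta-\beta')\,dt + \epsilon\sqrt{2D}\,dw$ with
  $\Lambda = \bar h/A$, diffusion $D$ from the noise correlation
  $C(\theta)=a\delta(\theta)+b\cos\theta$, and coupling $K$ in closed
  form (model A) or from the overlap potential $\phi$ (model B).
* **Circular statistics** — the stationary phase density is von Mises
  with $\kappa = \bar h/(\epsilon A D)$; mean tuning
  $A\,(I_1/I_0)(\kappa)\cos\theta$; M-shaped variance tuning; the
  bivariate cosine-model von Mises
  $\propto e^{\kappa_1\cos\beta_1+\kappa_2\cos\beta_2+
  \chi\cos(\beta_1-\beta_2)}$ with Bessel-series normalization,
  marginals, modality, Gaussian limit, and correlation tuning; and the
  generalized model-B density for surround modulation.
* **Simulation** — fast (C++) Euler–Maruyama integrators for the full
  field and the reduced SDEs, spatially structured noise, phase
  extraction, and ensemble statistics, so the analytics and the
  simulator cross-validate each other.
* **Experiments/CLI** — canned figure-level experiments with config
  echo and reproducible seeds (`exec/ringwander`, subcommands `bump`,
  `reduce`, `simulate`, `stats`, `experiment`, `validate`).

See `vignettes/ringwander-methods.Rmd` for the model, conventions
(including the noise-scaling convention and its consequences), numerics
and limitations.

## Worked example

```r
library(ringwander)

rp  <- ring_params(weight_amplitude = 1, gain = 4, threshold = 0.5)
solve_bump(rp)[[2]]
#> bump_solution: A = 1.849962 (stable), lambda_0 = 0, lambda_e = -0.817864

red <- build_phase_reduction(rp, stimulus_params(contrast = 2),
                             noise_params(0.05, 3, 0.5))
red
#> phase_reduction: Lambda = 1.08110, D = 0.74571, model = none, kappa = 28.9953, chi = 0.0000
```

The stable bump amplitude is $A \approx 1.85$; with contrast
$\bar h = 2$ the reduced phase process has drift amplitude
$\Lambda = \bar h/A \approx 1.081$, diffusion $D \approx 0.746$, and a
stationary von Mises concentration $\kappa = \bar h/(\epsilon A D)
\approx 29$ — a bump tightly locked to the stimulus.  Variance tuning
is M-shaped (normalized variance at the stimulus direction vs the
flanks):

```r
vm <- as_von_mises(red)
round(tuning_variance(c(0, pi/2), A = 1, vm), 4)
#> [1] 0.0006 0.0339
```

Excitatory vertical coupling between two layers suppresses phase
variance (model A, $\kappa = 2$):

```r
bivariate_moments(bivariate_cosine_model(2, 2, 0))$var_beta1  # 0.7645
bivariate_moments(bivariate_cosine_model(2, 2, 5))$var_beta1  # 0.3545
```

And the reduced SDE relaxes to the analytic density (here a
fast-mixing parameterization of $\kappa = 2$):

```r
traj <- simulate_phase_sde(phase_reduction(1, 1, epsilon = 0.5),
                           duration = 2000, seed = 1, save_every = 1)
ensemble_stats(traj$phases, traj$times, burn_in = 100)
#> ensemble_stats: 1 realization(s), 1900 pooled phases, resultant = 0.701, circular mean = -0.054
phase_tv_distance(traj$phases[traj$times > 100, ], von_mises(2))
#> [1] 0.0489
```

(The resultant of a von Mises law with $\kappa = 2$ is
$I_1(2)/I_0(2) \approx 0.698$.)

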