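---
title: "Gaussian-process bootstrap mechanism discovery for cell invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process bootstrap mechanism discovery for cell invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechdisc)
```

## The model and its assumptions

`mechdisc` fits one-dimensional invasion models

$$\frac{\partial u}{\partial t} = T(t;\alpha)\left[\frac{\partial}{\partial x}\left(D(u;\beta)\frac{\partial u}{\partial x}\right) + R(u;\gamma)\right],$$

to spatiotemporal cell-density data with zero-flux boundary conditions.
The three mechanisms have parametric libraries: the delay $T \in (0,1]$
(none, logistic, probit, or complementary log-log in $t$) multiplies
migration and proliferation equally and represents the temporary
disruption of cell function after scratching; the diffusivity $D(u)$
(constant, $\beta_2 u/K$, generalised $\beta_1+\beta_2(u/K)^{\beta_3}$, or
a two-power extension) models density-dependent migration; the reaction
$R(u)$ (logistic, Gompertz, Richards) models proliferation. The carrying
capacity $K$ is the one directly measurable quantity and is held fixed.
The default five-model catalog pairs no-delay/logistic-delay with the
constant and degenerate diffusivities plus the delayed generalised form,
all with logistic proliferation. The two-power diffusivity is implemented
but excluded from the default catalog because its extra parameters are
poorly identifiable from data of this sparsity.

The observation model is additive homoscedastic Gaussian noise,
$u_{obs} = u^*(x,t) + \sigma_n z$. All inference targets the de-noised
field $u^*$, not the noisy observations.

## Working units

Raw data arrive in micrometres, hours, and cells per square micrometre;
these scales differ by many orders of magnitude and destabilise both the
GP likelihood and the parameter optimisation. Internally everything runs
in working units: $x$ in mm (divide by $10^3$), $t$ in days (divide by
24), $u$ multiplied by $10^6$, and GP inputs further normalised to the
unit square. Reported parameters are converted back: rates in h$^{-1}$
(divide the working value by 24), diffusivities in $\mu$m$^2$ h$^{-1}$
(multiply by $10^6/24$), delay intercepts and exponents unchanged.

## The surrogate

A zero-mean GP with a separable squared-exponential kernel
($\sigma_f, \sigma_n, \ell_1, \ell_2$) is fitted by maximum marginal
likelihood with BFGS on log-parameters (positivity by transform; the
optimisation itself is unconstrained, so optima may leave the start box).
Starts come from a Latin hypercube over $\ell \in [10^{-6}, 1]$ and
$\sigma \in [10^{-6}, 7\,\mathrm{SD}(u)]$; the default is 250 restarts
(`fit_hyperparameters()`), and the best marginal likelihood wins. The
analytic gradient of the marginal likelihood is supplied, so each restart
costs a few dozen Cholesky factorisations of the $NM\cdot$Rep training
matrix.

Because differentiation is linear, the joint distribution of
$(u^*, \partial u^*/\partial\tau, \partial u^*/\partial\xi,
\partial^2 u^*/\partial\xi^2)$ on an $n \times m$ test grid is Gaussian
with cross-covariances given by closed-form kernel derivatives (up to
second order per argument in space, first order in time). These are coded
explicitly rather than by automatic differentiation so that the
finite-difference comparison in the test suite is a genuinely independent
check. The posterior covariance omits the observation-noise term — the
surrogate models the underlying function, not the data. Before the
Cholesky factorisation, each of the four diagonal blocks receives a nugget
$\eta_i = \eta\,\mathrm{tr}(\Sigma_{ii})/\mathrm{tr}(\Sigma_{11})$ with
base $\eta = 10^{-5}$: derivative blocks live on much larger scales, and
the trace ratio keeps the relative perturbation comparable. If the factor
still fails, $\eta$ escalates tenfold with a warning; a surrogate whose
function block has zero prior trace is an error, not something to mask.

Draws are $U = \mu + Lz$ with $z \sim N(0, I)$; the derivative blocks are
mapped from unit-interval to physical scales by $1/(t_M-t_1)$,
$1/(x_N-x_1)$, and $1/(x_N-x_1)^2$. All draws flow through a seeded
registry (`draw_registry()`), which is what makes ensembles bit-for-bit
reproducible and lets candidate models consume identical draws.

## Loss, feasibility, and estimation

For each draw, parameters minimise
$\log \mathcal{L}_{PDE} + \log \mathcal{L}_{GLS}$. The PDE-residual loss
is the mean squared residual of the expanded model
$\partial u/\partial t - T(t)[D'(u)(\partial u/\partial x)^2 +
D(u)\,\partial^2 u/\partial x^2 + R(u)]$ over the sampled grid; the GLS
loss is the mean of $w_j((\hat u_{ij}-u_{ij})/\sigma_n)^2$ over the data
grid, with $u_{ij}$ the replicate-averaged data, $\sigma_n$ the fitted GP
noise SD, and $w_1 = 10$, $w_{j>1} = 1$ so the initial profile — which
need not satisfy the governing model — is weighted up. The two losses live
on different scales, which is why they are combined on the log scale.
Replicate averaging in the GLS residuals is a deliberate choice: it
matches the residuals used by the error metric and the information
criterion, so all three quantities share one definition.

Mechanisms inside the residual are evaluated at $\max(u^*, 0)$: surrogate
draws can dip slightly below zero where the well is near-empty, and
fractional-power diffusivities are undefined there; the clip mirrors the
rule used for sampled initial conditions, and $D$ itself is never clamped.

Feasibility is a hard barrier: evaluation of $T$ on the time grid, $D$
over the sampled density range (100 points), and the Gauss–Legendre
integral (64 nodes) of $R$ over $[0, \max u^*]$ must all be non-negative,
and the finite-volume solve must succeed; otherwise the loss is $+\infty$
and the optimiser treats the trial point as rejected. Optimisation uses
Nelder–Mead (robust to the infinite barrier) with a chained restart —
the simplex is re-run from its solution until no further improvement —
capped at 500 iterations per round.

Starting values follow a pilot/main scheme. The pilot phase (default 10
draws) uses 5 Latin-hypercube starts per draw over rough per-parameter
boxes: log-uniform on $[10^{-3}, 10^3]$ for positive-kind parameters
(rates, diffusivities), uniform on $[-10, 10]$ for sign-free ones (delay
intercepts, exponents). The geometric mean of the pilot estimates, with
the pilot median's sign, becomes the per-parameter scale; main draws then
optimise $\theta/\mathrm{scale}$ from the all-ones start. The sign matters:
an unsigned scale would start the delay intercept in the wrong orthant.
For delay-free models whose mechanisms are linear in the parameters,
`linear_basis_fit()` solves the stacked residual system by least squares —
no PDE solves, useful for quick scale estimates, but it ignores the data
loss and therefore carries larger PDE-solution errors.

Optional data thresholding (`threshold_data()`) masks grid points whose
sampled density or rate of change falls outside `[low, high]` fractions of
the respective field maximum; the mask applies to the PDE-residual sum
only. Fractions of the maximum (rather than absolute cutoffs) are used so
thresholds transfer across datasets; it is off by default.

## The finite-volume solver

The PDE is semi-discretised by a vertex-centred finite-volume scheme on
$N_p$ equally spaced nodes: half control volumes at the boundaries, face
diffusivities by arithmetic averaging, first-order gradients — with
$R \equiv 0$ the scheme conserves $\sum_i V_i u_i$ exactly, and it
converges at second order in $\Delta x$. Time integration is lsoda with a
tridiagonal (banded) Jacobian, relative tolerance $10^{-6}$ and absolute
tolerance $10^{-8}$ (the method is insensitive to these; both are
configurable). The right-hand side used by the integrator is a compiled
kernel — each bootstrap draw needs hundreds of solves, and per-step R
overhead would dominate otherwise — cross-checked in the test suite against
the plain-R reference implementation. Inside the kernel, $D$ and $R$ are
evaluated at $\max(u, 0)$ (the flux uses the raw state): small negative
undershoots near steep fronts are mesh artifacts, and fractional-power
diffusivities are undefined there. During fitting the integrator is
additionally capped at 1000 internal steps per output interval, so
pathological trial parameters fail fast instead of consuming unbounded
solver effort. Solutions are read off at data coordinates by nearest-node
extraction with ties broken toward the lower index. Integration failures
from pathological trial parameters return a flagged solution that the loss
maps to $+\infty$; they never abort a bootstrap draw. Initial conditions
are either a linear interpolant of the replicate-averaged $t=0$ profile
(`spline_ic()`) or, in the bootstrap, the draw's own $t=0$ slice with
negative values clipped to zero (`sampled_ic()`); estimating the initial
state alongside the parameters is what lets the ensemble's solution
ribbons capture the data.

## Bootstrap summaries and model selection

The $B$ per-draw estimates (default $B = 100$) give percentile intervals
(type-7 quantiles at 2.5/97.5%, bit-reproducible), kernel-density modes
(Gaussian kernel, Silverman bandwidth, 512-point grid, ties to the lower
value), pointwise ribbons for $T$, $D$, $R$, MAPE intervals (per-draw
median of $100|\hat u_{ij}-u_{ij}|/\max(\zeta, u_{ij})$ with $\zeta$
machine precision guarding empty cells), and closed-interval CI hypothesis
tests (a null at an endpoint is not rejected). Failed draws are dropped
from summaries with a logged count, never imputed; an ensemble with more
than half its draws failed is an error.

Model comparison uses the small-sample-corrected AIC of the sampled-IC
solution residuals, $AIC = NM\log(SSR/NM) + 2(k+1)$ with
$k = a + d + r$, corrected by $2(k+1)(k+2)/(NM-k)$. Because all models
share the draw registry, per-draw differences
$\Delta_i^{(b)} = AICc_i^{(b)} - \min_j AICc_j^{(b)}$ are paired;
$\Delta \le 3$, $3 < \Delta \le 8$, $\Delta > 8$ classify evidence into
$E_1/E_2/E_3$, and the proportions over draws form the $3\times|M|$ matrix
$P$ whose columns sum to 1 (rows need not — several models can share the
best class). Draws in which any model failed are excluded for all models
to keep the pairing intact.

## The synthetic-data generator

`generate_study()` emulates the study shape of a scratch assay: 37
positions on $[75, 1875]\ \mu$m, times $\{0, 12, 24, 36, 48\}$ h, 3
replicates, $K = 1.7\times10^{-3}$ cells $\mu$m$^{-2}$, additive
$N(0, \sigma_n^2)$ noise per replicate with negative values retained. The
preset noise level is $\sigma_n = 0.05K$, a mid-range value for
column-count densities of this kind. The initial profile is a symmetric
tanh-ramp well (`scratch_ic()`, plateau $0.5K$ at the edges, $0.02K$ in
the depleted centre, transitions at 20% of the domain) standing in for a
measured pre-scratch profile; it reproduces the qualitative features —
edge plateaus, near-empty centre — but not the asymmetry or
spatially-correlated counting noise of real wells. Passing tests on this
generator therefore demonstrate correct mechanics and recoverability under
idealised noise, not performance on any particular experimental dataset.
The two presets generate from the constant-diffusivity logistic model
($\beta_1 = 301\ \mu$m$^2$h$^{-1}$, $\gamma_1 = 0.044$ h$^{-1}$) and its
logistic-delay variant ($\alpha_1 = -1.5$, $\alpha_2 = 0.31$ h$^{-1}$,
$\beta_1 = 571\ \mu$m$^2$h$^{-1}$, $\gamma_1 = 0.081$ h$^{-1}$).

## Problem sizes and numerical choices

The test suite and the reproduction script run a scaled-down protocol
chosen as the smallest configuration at which recovery is stable: 25
hyperparameter restarts, a $30\times30$ surrogate grid, $B = 30$ draws
with a 10-draw pilot, and a 50-node mesh. The full-scale defaults (250
restarts, $50\times50$ grid, $B = 100$, $N_p = 500$) remain the function
defaults. Mesh-resolution insensitivity is checked explicitly: recovery at
$N_p = 50$ and $N_p = 500$ yields overlapping confidence intervals.

## Known limitations

- **Delay identifiability.** With only five observation times, the GP's
  temporal smoothing cannot represent a sharp post-scratch transient: the
  sampled $\partial u/\partial t$ near $t = 0$ is systematically too
  large, so delay parameters are weakly identified and their sampling
  distributions shrink toward shallower delays ($|\alpha_1|$, $\alpha_2$
  biased low) even when the optimiser demonstrably reaches lower loss than
  the generating truth. Diffusivity and proliferation rates are robust to
  this; conclusions about delay timing from data this sparse deserve
  caution, and more observation times (not more bootstrap draws) are the
  remedy.
- The zero-mean GP does not know the zero-flux boundary conditions, so
  sampled curvature near the domain ends carries a boundary artefact.
- Homoscedastic noise is assumed throughout; densities pinned near the
  carrying capacity violate it.
- One spatial dimension only; no advection, no moving boundaries, no
  kernel families beyond the squared exponential.
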