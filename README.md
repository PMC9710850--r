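# mechdisc

Mechanism discovery with uncertainty quantification for one-dimensional
cell-invasion experiments.

## The problem

In a scratch assay, a strip is scraped out of a cell monolayer and the
re-invasion of the gap is imaged over a couple of days. The resulting data
are sparse and noisy: a few dozen column-averaged densities u(x, t) at a
handful of times, in a few replicate wells. The modelling question is which
mechanisms drive the invasion: is cell migration density-independent
(linear diffusion) or density-dependent? Is proliferation logistic? Is
there a post-scratch delay before cells resume normal migration and
proliferation? `mechdisc` addresses these questions for reaction–diffusion
models of the form

    du/dt = T(t; α) [ d/dx ( D(u; β) du/dx ) + R(u; γ) ],

with zero-flux boundaries, where T ∈ (0, 1] is a delay factor scaling
migration and proliferation equally (e.g. logistic,
T = 1 / (1 + exp(−α₁ − α₂ t))), D(u) is a nonlinear diffusivity (constant
β₁; degenerate β₂ u/K; or the generalised form β₁ + β₂ (u/K)^β₃), and R(u)
is a proliferation law (logistic γ₁ u (1 − u/K), Gompertz, or Richards),
with the carrying capacity K fixed at its measured value.

## The method

1. **Gaussian-process surrogate.** A zero-mean GP with squared-exponential
   kernel is fitted to the rescaled density data by multistart maximum
   likelihood. Because differentiation is linear, the joint posterior of
   (u*, ∂u*/∂t, ∂u*/∂x, ∂²u*/∂x²) on a test grid is Gaussian with
   covariance blocks given by analytic kernel derivatives; a block-scaled
   nugget stabilises its Cholesky factor.
2. **Parametric bootstrap.** Each draw z ~ N(0, I) produces a sampled field
   and derivatives U = μ + Lz. For each draw, θ = (α, β, γ) is estimated by
   minimising log L_PDE + log L_GLS, where L_PDE is the mean squared
   residual of the expanded PDE over the sampled grid and L_GLS is the
   weighted mean squared data-vs-solution residual standardised by the
   fitted noise SD (the PDE is solved by a vertex-centred finite-volume
   method with stiff adaptive time stepping, from an initial condition
   sampled from the GP). Physically infeasible parameters (negative delay
   or diffusivity, negative integrated reaction) receive infinite loss.
3. **Uncertainty and selection.** The B estimates give percentile
   confidence intervals, kernel-density modes, ribbons for the functional
   forms and PDE solutions, and median-absolute-percentage-error (MAPE)
   intervals. Candidate models consume identical draws z⁽ᵇ⁾, so per-draw
   AICc differences Δ are paired; Δ ≤ 3, 3 < Δ ≤ 8, Δ > 8 define an
   evidence trichotomy whose bootstrap proportions form the selection
   matrix P.

A synthetic-data module generates scratch-shaped datasets from known
mechanisms so the entire pipeline is testable without experimental data.

## Worked example

Generate a synthetic Fisher–Kolmogorov dataset (β₁ = 301 μm² h⁻¹,
γ₁ = 0.044 h⁻¹, 37 positions × 5 times × 3 replicates, additive noise) and
re-estimate the parameters:

```r
library(mechdisc)

design <- study_presets()$study1
data <- generate_study(design)             # raw units: um, h, cells um^-2
fit <- fit_surrogate(data, n = 30, m = 30, restarts = 25, seed = 1)
model <- mechanism_model("none", "constant", "logistic", K = 1700)
ens <- run_bootstrap(fit$surrogate, model, fit$data,
                     B = 30, seed = 1, Np = 50)
ensemble_summary(ens)
#>   parameter           lo           hi         mode
#> 1     beta1 179.98349040 305.77655232 255.61517759
#> 2    gamma1   0.04159769   0.04476309   0.04215319
mape_interval(ens)$interval
#>       lo       hi
#> 6.280274 8.809255
```

The summary rows are 95% percentile confidence intervals and
kernel-density modes for the cell diffusivity (μm² h⁻¹) and proliferation
rate (h⁻¹): both intervals cover the generating values, and the MAPE
interval says the learned PDE solutions sit within roughly 6–8% of the
replicate-averaged data. Fitting the five-model catalog with
`select_models()` (shared draws) adds the evidence matrix `P`; for data
generated with a delay, the delayed Fisher–Kolmogorov model attains the
largest P(E1).

A command-line entry point for external data files is installed at
`system.file("exec", "mechdisc.R", package = "mechdisc")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","mechdisc.R",package="mechdisc"))')" \
  --data densities.csv --models all --drop-leftmost --B 100 --out results/
```

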