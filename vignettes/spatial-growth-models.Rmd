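---
title: "Modelling spatially coupled colony growth with a latent resource field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatially coupled colony growth with a latent resource field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput solid-medium platforms pin hundreds to thousands of microbial
colonies onto a single agar plate (canonically a 32 x 48 grid, 1536 colonies)
and image them every 20 minutes for 72 hours, yielding a population-size
estimate $N_i(t)$ for every colony $i$ at 218 time points. Although the
colonies are isogenic and the medium initially homogeneous, growth varies
strongly and systematically with position: colonies near the grid border end
up substantially larger than interior ones, because they border colony-free
agar whose nutrients diffuse toward them. Treating this merely as technical
bias discards ecology; `platekin` models it explicitly, so that intrinsic,
strain-specific growth parameters can be separated from the shared
environment.

Two preprocessed summaries drive every analysis: the absolute growth rate
$\Delta N_i(t) = (N_i(t) - N_i(t-1))/\Delta t$ (backward difference, time in
20-minute steps) and the relative, per-capita rate
$\rho_i(t) = \Delta N_i(t) / N_i(t)$. Curves are smoothed with a moving
average and the final samples are discarded before any derivative is taken
(`smooth_series()`, `compute_rates()`).

## The model hierarchy

The package fits a nested sequence of models for $\hat\rho_i(t)$, each adding
one ingredient, so that the error removed at each step can be attributed to a
specific mechanism (`sse_decompose()` provides per-colony and per-time views,
`aic()` the parameter-count-aware comparison):

1. **Null**: $\hat\rho_i(t) = \epsilon(t) = \bar\rho(t)$, the plate mean. No
   colony identity, no space.
2. **Adjustment + global multiplier** ($\alpha\epsilon$): the
   Baranyi-Roberts-type lag adjustment
   $\alpha_i(t) = r_0\, c_i / (c_i + e^{-m t})$ modulates a shared
   mechanism-free multiplier: $\hat\rho_i(t) = \alpha_i(t)\,\epsilon(t)$.
   Here $r_0$ is the plate-global maximum growth rate, $m$ the global rate at
   which cells leave the lag state, and $c_i$ the colony-specific initial
   physiological state ($c_i$ small means a long lag). Early in the
   experiment the colonies have not yet competed for resources, so treating
   $r_0$ and $m$ as global is justified.
3. **Layered multiplier** ($\alpha\epsilon_k$): $\epsilon$ becomes
   $\epsilon_k(t)$, one series per border-distance layer $k$ (16 layers on a
   32 x 48 grid; `layer_index()`), capturing the border-to-centre gradient
   without a mechanism.
4. **Density-dependent consumer-resource** ($\alpha\epsilon_k s$): a latent
   local resource $s_i(t)$, consumed in proportion to growth
   ($\mathrm{d}s_i/\mathrm{d}t = -\nu\,\mathrm{d}N_i/\mathrm{d}t$), enters
   multiplicatively: $\hat\rho_i = \alpha_i \epsilon_k s_i$ with
   $s_i(t) = \exp(-\nu \int_0^t \alpha_i \epsilon_k N_i\,\mathrm{d}t')$ and
   $s_i(0) = 1$ (resource units are arbitrary). With constant $\alpha$ and
   $\epsilon$ this is exactly logistic growth.
5. **Diffusion model**: the layered multiplier is replaced by a physical
   process. A single resource field $s(x, t)$ lives on the plate lattice,
   extended by three colony-free padding layers on every side (38 x 54 for
   the full grid), and evolves by
   $\partial s/\partial t = D \nabla^2 s - F(N_i)$ with the consumption term
   $F(N) = \nu_1\,\mathrm{d}N/\mathrm{d}t + \nu_2 N$ (growth-coupled plus
   maintenance consumption). The Laplacian is coarse-grained to its
   mean-field lattice form $D(\bar s - s)$, with $\bar s$ the Moore-8
   neighbour mean (`mean_field_neighbors()`). Growth couples to the resource
   through $f(s) = (1 + e^{-K s})^{-\kappa}$, giving
   $\hat\rho_i(t) = \alpha_i(t) f(s(x_i, t))$. The model has seven global
   parameters ($r_0, m, D, \nu_1, \nu_2, K, \kappa$) plus one local $c_i$ per
   colony.

### Why the resource may run negative

$s$ is latent: adding any constant $s^*$ to $s(0)$ while evaluating the
coupling at $f(s - s^*)$ leaves every prediction exactly invariant
(`predict_rho_diffusion(..., s_star = )`; the property suite verifies this at
machine precision). The scale is fixed only by the $s_0 = 1$ convention. In
the glucose parameter regime ($K \approx 16.8$, $\kappa \approx 0.007$) the
coupling is essentially 1 for all $s \ge 0$ and decays like
$e^{\kappa K s}$ for $s < 0$: the fitted dynamics deliberately drive $s$
through zero and beyond, which is meaningful precisely because $s$ carries an
arbitrary additive constant. For this reason the integrators do **not** clip
$s$ at zero by default (`clip_s`/`clip` arguments exist for experimentation);
with clipping enabled, the glucose parameter set would never leave the
exponential phase.

## Fitting protocols

**Adjustment (two-stage, `fit_alpha_two_stage()`).** Stage 1 fits
$(r_0, m, c)$ per colony by bounded Levenberg-Marquardt on the early window
of each $\rho_i$ curve — all samples up to the colony's rate maximum, where
the environment is still near-homogeneous (initial values $r_0 = \max\rho_i$,
$m = 0.3$, $c = 0.05$; bounds keep all parameters positive). Stage 2 takes
the plate-global $r_0$ and $m$ as medians of the converged local fits (the
aggregation statistic is a package choice; the median is robust to the
occasional degenerate colony fit). Stage 3 refits each $c_i$ with the global
rates fixed, by golden-section search on $\log c$. Colonies whose local fit
fails are flagged, excluded from the medians, and still receive a stage-3
$c_i$.

**Mechanism-free multipliers (`fit_eps()`).** With $\alpha$ fixed the model
is linear in $\epsilon$ at each time point, so the least-squares solution is
closed form, $\epsilon = \sum \alpha\rho / \sum \alpha^2$, per plate or per
layer, clamped at zero (the multiplier is a growth factor).

**Density model (`fit_density_model()`).** Alternating minimisation starting
from the $\alpha\epsilon_k$ solution. The $\nu$ step is *profiled*: for each
candidate $\nu$ the resource field is integrated with the current
$\epsilon_k$ in the integrand and the layered multiplier is refit in closed
form before scoring. This matters: optimising $\nu$ against a frozen
$\epsilon_k$ collapses to $\nu = 0$, because the layered multiplier has
already absorbed the layer-mean resource decline and $\nu$ is identified only
through within-layer, between-colony differences in cumulative consumption.
The adjustment parameters are recomputed against the current
$\epsilon_k \cdot s$ background every iteration. Iterates are accepted only
if the SSE does not increase; the loop stops at a relative improvement below
`tol = 1e-6`, at 50 iterations, or after three non-improving proposals
(returning the best iterate with a warning; a negligible non-improvement is
treated as a converged coordinate fixed point).

**Diffusion model (`fit_diffusion()`).** A doubly iterative scheme. The
outer search optimises $(D, \nu_1, \nu_2, K, \kappa)$ by Nelder-Mead in
log-parameter space (three starts with fixed seeds, log-normal perturbations
of a data-driven initial guess; candidates violating the mean-field
stability bound $D \le 1$ per step are rejected with a penalty). Each
candidate is scored by integrating the latent field under the *observed*
population sizes at the 20-minute step (`integrate_resource()`) and
comparing $\alpha f(s)$ with the measured rates. The inner iteration of the
original protocol — freeze $\bar s$, integrate $s$, recompute $\bar s$,
repeat until predictions stop improving — has as its fixed point exactly the
one-pass explicit Euler recursion in which $\bar s$ at step $t$ is taken
from the current slice; the package integrates directly by default and
ships the sweep as `method = "sweep"` (a test asserts both agree to 1e-8).
After each optimiser round the adjustment parameters are recomputed against
the current coupling background $f(s)$, and rounds repeat until the SSE
stops improving (relative tolerance 1e-6, at most 6 rounds).

## The forward simulator and synthetic data

`simulate_plate()` co-integrates colony growth
$\mathrm{d}N_i/\mathrm{d}t = \alpha_i(t) f(s(x_i,t)) N_i$ and the resource
field on the padded lattice with explicit Euler at a tenfold finer step
(2 minutes), then subsamples to the 218-point/20-minute grid. Inference-mode
integration stays at the 20-minute step, matching the fitting protocol.

`generate_plate()` wraps the simulator into a reproducible generator whose
defaults emulate the reference experiment:

* **Global parameters** come from `growth_param_table()`, the reference
  parameter set per condition; diffusivities are converted from cm$^2$/s to
  lattice units via the 2.25 mm colony pitch and 20-minute step
  (`lattice_diffusivity()`; 3.60e-6 cm$^2$/s corresponds to 0.085 pitch$^2$
  per step). The pitch is taken as the grid extent 105.75 mm divided by 47
  inter-colony gaps.
* **Initial population sizes** are log-normal around 1e4 (arbitrary
  calibrated units, so that plates saturate within the 72 h window in the
  glucose regime) with i.i.d. CV 0.15 plus log-scale row and column effects
  (s.d. 0.2), emulating pre-culture structure shared along rows/columns.
* **Physiological states** are log-normal around $c = 0.01$ (a lag of
  $\log(1/c)/m \approx 11$ steps in glucose), CV 0.5, with row/column
  effects (s.d. 0.3) and box-smoothed spatial noise — giving $c_i$ the
  smooth spatial structure that makes position predictive of early growth.
  `c_model = "plate_mean"` removes all state variability, the scenario used
  to show that early position importance in the ML analysis is state-driven.
* **Occupancy** is full by default; `"every_fourth"` keeps only the
  bottom-right cell of every 2 x 2 block.
* **Noise** defaults to zero: the generator's primary role is noiseless
  parameter-recovery testing. Multiplicative log-normal observation noise is
  available.

What the generator does *not* emulate: image-analysis artefacts, the
calibration function of the acquisition platform, plate-edge drying,
condition-dependent pre-culture magnitudes (the row/column effect sizes are
free knobs chosen once at plausible values, since the reference data
quantify them only qualitatively). Passing recovery tests on these plates
therefore demonstrates self-consistency of the inference, not robustness to
real measurement noise.

## Numerical choices

* **Time unit**: one sampling step (20 minutes) everywhere; rates are
  reported per step.
* **Smoothing**: trailing moving average (window-end aligned), window 10 and
  10 discarded tail points by default; alignment is configurable. The
  window-10 default exists to suppress measurement noise in platform data.
  On *noiseless* simulated plates the 10-sample boxcar smears the coupling
  transition around $s = 0$ and measurably biases the deceleration-phase
  parameters (it lowers the apparent $m$ and displaces the SSE optimum in
  $\nu_1$ upward by tens of percent); the package's recovery studies
  therefore preprocess synthetic plates with `window = 2`, which preserves
  the backward-difference convention while leaving the transition intact.
* **Masking**: rates at non-positive population sizes are `NA` (excluded
  from all fits), never zero-filled, so early empty wells cannot dominate
  the SSE.
* **Quadrature**: the density-model resource integral uses cumulative
  trapezoids by default (`"left"` mirrors plain Euler); a test checks the
  trapezoid against an adaptive ODE solution to 1e-4.
* **Boundaries**: the padded lattice uses averages over existing neighbours
  at its outer edge (an approximate closed-wall condition); a torus option
  exists for conservation tests, where total resource is conserved exactly.
* **Ties and degeneracies**: the rate-maximum window end takes the earliest
  maximum; a perfect fit's AIC is guarded by an SSE floor; constant ML
  targets report `NaN` R$^2$ with a warning; negative test R$^2$ is reported
  as-is.
* **Problem sizes**: the test and acceptance runs use 8 x 12 mini-plates
  (2 padding layers) for the model-hierarchy and ML analyses and a reduced
  16 x 24 grid (3 padding layers, full 218-sample series) for
  simulate-and-refit recovery — large enough to retain genuine spatial
  layering while keeping a full doubly-iterative fit around a minute.

## Known limitations

* $\nu_2$, $K$ and $\kappa$ compensate one another (the deep-starvation
  regime constrains mainly the products $\kappa K$ and $\kappa K \nu_1$);
  recovery is asserted for $r_0$, $m$, $D$ and $\nu_1$ only, and the
  remaining three are checked through the quality of the fitted rates.
* The estimates of $r_0$ inherit a small negative bias (about the ratio
  $(1 - e^{-\rho})/\rho$ at peak rate, roughly 6% in glucose) from the
  backward-difference definition of the measured rates; it is well inside
  the recovery tolerance and shared by any analysis using the same rate
  convention.
* Monod-form coupling is not offered in the diffusion fit: the linearised
  regime is assumed throughout the density model, and the sigmoid family is
  the supported nonlinear coupling.
* A single latent resource dimension is assumed; plates mixing strains with
  very different resource usage would need a richer latent space.
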