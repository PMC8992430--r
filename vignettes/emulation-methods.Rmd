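---
title: "Emulation methods for spiking-neuron simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulation methods for spiking-neuron simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuremu)
```

This vignette is the package's account of its science: the models it
implements, the synthetic study conditions it runs them under, the numerical
and design choices that were genuinely open, and what the package's tests do
and do not establish.

## 1. The problem setting

Feature-based multi-objective fitting of neuron models couples three parts:
a simulator mapping a parameter vector to voltage traces, a feature extractor
mapping traces to electrical features, and a genetic algorithm minimizing the
summed feature distance to experimental targets,

$$\text{Global score} = \sum_j \left| \frac{f_{j,\mathrm{sim}} -
\mu_{j,\mathrm{exp}}}{\sigma_{j,\mathrm{exp}}} \right|,$$

with each term in units of the experimental SD so that features of different
magnitudes contribute comparably. The simulator dominates the cost; the
package studies how statistical emulators can replace or screen simulator
calls inside the loop, and what inference the emulators support.

## 2. The stand-in simulator

Realistic compartmental simulations are out of scope; the package ships a
deterministic adaptive-exponential integrate-and-fire membrane,

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T
e^{(V - V_T)/\Delta_T} - w + k\,I(t), \qquad
\tau_w \dot w = a_w (V - E_L) - w,$$

with a spike registered when $V$ reaches the cutoff $V_\mathrm{peak}$
(recorded at the cutoff for one sample, then reset to $V_\mathrm{reset}$,
$w \mathrel{+}= b_w$, refractory clamp $t_\mathrm{ref}$). This model is chosen
because it produces *genuine* values for spike-shape and inter-spike features
and *natural structural missingness* — a cell that never spikes has no peak
voltage; a cell with one spike has no inter-spike minimum — at negligible
cost. It stands in for a biophysical simulator structurally, not
biophysically.

Twelve mechanistic parameters are padded with inert dimensions (default total
$d = 31$, the dimensionality typical of conductance-fitting problems). Inert
parameters are provably ignored by the integrator; they double as built-in
negative controls for variable-importance and sensitivity analyses.

The parameter box was calibrated once to basket-cell physiology — input
resistance 100–400 MΩ ($g_L \in [0.0025, 0.01]\,\mu S$), membrane time
constant ~10–30 ms, $E_L \in [-85, -65]$ mV, threshold in $[-55, -40]$ mV —
so that the suprathreshold protocol (0.27 nA, 2000 ms) elicits repetitive
firing over most of the box while the weak protocol (0.04 nA, 1000 ms) stays
subthreshold. At these defaults a random first generation has roughly 14% of
individuals that never spike and 21% with fewer than two spikes: structural
missingness in both directions, which is what the two-stage pipeline needs.

Numerical choices: fixed-step explicit Euler, default `dt = 0.1` ms
(config-exposed); halving the step changes features by well under 1% in the
interior of the box. The exponential upswing is capped at 40 e-folds — the
cutoff fires the same step, so the cap never affects recorded values. Units
are ms/mV/nA/nF/µS throughout; windows are half-open `[start, end)` over
0-based samples.

Feature windows (config-exposed; common electrophysiology practice, since no
single convention exists): `voltage_base` = mean over the 100 ms before
onset; `steady_state_voltage_stimend` = mean over the last 10% of the
stimulus; `voltage_after_stimulation` = mean over the last 100 ms of the
trace. Spike-dependent features and their missingness contract are listed in
`?extract_features`.

## 3. The emulators

All emulators share one prediction contract (`mean, sd, q05, q95`), operate
on inputs scaled to the unit cube via the parameter-space bounds, and
standardize the response internally (the scaling scheme is ours; some scheme
is required for a shared ARD kernel across heterogeneous units).

**Gaussian process.** Regression-plus-GP form $f(x) = \sum_i \beta_i g_i(x)
+ Z(x)$ with a constant trend by default and the ARD squared-exponential
kernel. Hyperparameters ($\log l_j$, $\log \sigma_f^2$, $\log \sigma_n^2$)
maximize the $\beta$-profiled log marginal likelihood by multi-start L-BFGS-B
with analytic gradients (compiled); the model then conditions on the
estimates (empirical Bayes). Defaults: 3 starts (one fixed at mid-range
lengthscales, the rest seeded log-uniform), `maxit = 100`, bounds
$l_j \in [10^{-3}, 10^3]$ (unit-cube units), nugget estimated in
$[10^{-8}, 1]$ on the standardized scale. The nugget is estimated by default
even though the simulator is deterministic, purely as a conditioning guard; a
fixed nugget of 0 gives an interpolator. Three starts (rather than more) is a
deliberate cost/robustness point: with analytic gradients the optimum at
these problem sizes is recovered reliably, and the lengthscale-recovery test
documents the residual multimodality risk. Cholesky failures climb a jitter
ladder ($0, 10^{-10}, 10^{-8}, 10^{-6}$ relative) and then error.

Predictions use the universal-kriging posterior including the
trend-estimation correction; the reported `sd` is the latent (noise-free)
predictive SD, and `q05`/`q95` are Gaussian quantiles at the configured level
(default 90%).

**GPllm.** Per-dimension data-driven choice of *linear trend* versus
*kernel*: greedy coordinate descent in index order from the all-GP model,
accepting a move to linear when it does not worsen the BIC on the marginal
likelihood by more than 2 units (near-ties resolve to the parsimonious linear
form). Comparison fits run on a seeded subsample (≤ 300 rows, warm-started,
single-start) because the decision is about functional form, not fine
hyperparameter values; the selected structure is refitted on all data with
the full budget. When ordinary least squares already fits to numerical
precision the model short-circuits to exact least squares — the GP's linear
limit.

**laGP.** For each prediction site, a GP on the `m = 50` nearest training
points (unit-cube Euclidean metric, ties by row index). Nearest-neighbor
subsetting is the simplest published variant of local approximation; the
package deliberately does not implement greedy design-point selection.

**Treed model.** Greedy recursive axis-aligned splits maximizing residual
variance reduction, with linear, GP or GPllm leaf models fitted
independently. This is a deterministic approximation to Bayesian treed GP
models: it keeps the two mechanisms that matter for bi-modal responses
(regime partition + flexible within-regime fit) and drops the MCMC tree
posterior, a documented simplification.

**Baselines.** Random forest (`randomForest`) and a small neural network
(`nnet`) provide point predictions only (`sd = NA`) and are excluded from
coverage analysis; a linear model and a train-mean null model complete the
benchmark set. The forest/net are delegated to their standard implementations
behind the shared contract.

## 4. The GA and its emulation strategies

Operators are standard real-coded choices, all config-exposed: tournament
selection minimizing the score, BLX-$\alpha$ blend crossover
($\alpha = 0.5$, rate 0.9), per-gene Gaussian mutation (probability $1/d$, SD
10% of each parameter's range), bound clipping, elitism 1. Two defaults were
set by the package after observing convergence behaviour on the stand-in
(and are the package's own choices, not reproductions): tournament size 4 and
a geometric anneal of the mutation SD (factor 0.90 per generation). With weak
selection pressure and a constant mutation scale the best score plateaus at a
mutation noise floor; the annealed schedule lets late generations fine-tune.
Selection *minimizes* the global score — the score is a distance, so "fitter"
means lower.

Missing features enter the score at a flat penalty (default 20 SD-units per
missing feature, config-exposed and deliberately prominent in the docs): the
penalty must dominate typical observed deviations so that individuals lacking
a defining event are strongly disfavoured. This is a package design decision;
no experimental value exists for it.

Strategies:

- **split** — per generation, a seeded 80% subset is simulated, one emulator
  per feature is fitted on it, the other 20% are emulated. Exactly
  $0.8 n$ simulator calls and $0.2 n$ emulator predictions per generation.
- **emulate_gens** — refresh generations are fully simulated and used to
  refit; intermediate generations are fully emulated except a simulated
  drift-check sample (default 20), whose per-feature RMSE in units of the
  current generation's feature SD triggers a refit above threshold (default
  0.5 — half an SD, the package's accuracy bar for a usable emulator).
- **screen** — the previous generation's emulators score all offspring; only
  the best keep-fraction is simulated, the rest are discarded unsimulated.

Per-feature emulators are independent (one response each); when several
candidate specs are supplied the best per feature is chosen on a seeded
internal 75/25 validation split. Emulator-evaluated individuals carry
emulator provenance and are never used as training data (no self-training
feedback), and the run-level best is tracked over simulator-verified
individuals only, so an optimistic emulated score can never be reported as
the optimum. Features whose training response is degenerate (constant) get a
constant emulator; features with too few observed rows trigger a logged
full-simulation fallback for that generation.

## 5. Inference

**Coverage.** The fraction of held-out values inside the closed interval
$[\hat q_{5\%}, \hat q_{95\%}]$, nominal level 0.90 (config-exposed).
Calibration is verified under the model's own assumptions: test responses
drawn from the fitted GP's predictive distribution are covered at the nominal
rate. This validates the quantile arithmetic and the variance computation; it
does not certify calibration on data the model misfits (with real misfit,
coverage drops — that regime needs real simulator data and is outside what
the synthetic tests can show).

**Sobol sensitivity.** Saltelli-scheme paired sampling (base sample a power
of two) with the Jansen estimators for first-order $S_j$ and total $T_j$
indices, applied to the emulator's posterior mean; $n_\mathrm{base}(d+2)$
emulator evaluations. The input distribution is uniform over the parameter
box — a distribution reflecting prior knowledge or relative interest (for
example a posterior over parameters) is pluggable, but none is available
here, so the box-uniform is the default. Two appended standard-normal noise factors act as negative controls:
any parameter whose index falls at or below the controls' is
indistinguishable from noise. Indices are reported clipped at zero with raw
values retained; averaging posterior variance rather than the mean is exposed
as an option and off by default. Main-effect curves fix one parameter on a
grid and average predictions over Monte-Carlo draws of the rest, with common
random numbers across the grid.

## 6. The two-stage missing-feature pipeline

A random-forest classifier is trained on the binary missingness indicator
over all rows; the value emulator is trained on observed rows only; at
prediction time rows classified missing get the missing token without a
regressor call. The decision threshold on the forest's observed-class vote
defaults to 0.5 and is config-exposed, because the pipeline's priority is
*sensitivity* (not discarding valid individuals) and a user may want to bias
the threshold toward predicting observed. When the minority class has fewer
than 10 training rows the classifier is skipped entirely — with a handful of
missing rows there is nothing to learn and every row goes to the regressor.
Optional tuning sweeps `n_trees` over {500, 800, 1100, 1200} and `mtry` over
{⌈√d⌉, 15, 24} by out-of-bag accuracy — a small grid around the tuned values
reported for such classifiers in the literature.

## 7. Study conditions and problem sizes

The test suite and the acceptance script run everything at desk scale, chosen
as the package's own study conditions: generations of 200–1000 individuals at
$d = 31$; emulator accuracy assessed at 800 train / 200 test; coverage at 500
predictive draws × 10 replicates; Sobol oracles at $n_\mathrm{base}$ =
1024–4096 and the stand-in sensitivity analysis at $n_\mathrm{base}$ = 512 on
350-individual fits; optimization sanity over 30 generations (full
simulation) and 20 generations (full-vs-split comparison), five seeds each.
In-GA emulator refits use single-start optimization — inside the loop the
hyperparameter surface moves slowly between generations, and the refit cost,
not the optimum's precision, is binding.

## 8. Known limitations

- The stand-in shares the *structure* of biophysical fitting problems
  (dimension, feature catalog, missingness, bi-modality), not their dynamics;
  passing tests demonstrate the methodology, not accuracy on any real
  neuron model.
- Feature emulation is univariate throughout; joint emulation across
  correlated features is deliberately out of scope.
- The treed model is greedy; it will not average over tree structures and
  can misplace splits on noisy low-contrast regime boundaries.
- GP hyperparameter optimization is multimodal; pathological optima
  (degenerate lengthscales) occur in a small fraction of seeds at 2–3 starts
  and are essentially eliminated at 5 starts — the lengthscale-recovery test
  quantifies this.
- Coverage calibration is verified under the model's own distribution only.
- Wall-clock timings in the benchmark table are hardware-dependent and
  carry no scientific claim.
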