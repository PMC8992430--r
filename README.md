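# neuremu

Statistical emulation and surrogate-assisted optimization for spiking-neuron
simulators.

## The problem

Fitting conductance-based neuron models to electrophysiology data is usually
posed as feature-based multi-objective optimization: a genetic algorithm (GA)
proposes populations of parameter vectors ("individuals"), a biophysical
simulator turns each individual into voltage traces, electrical features are
extracted from the traces, and each individual is scored by its distance to
experimental targets. With realistic simulators one generation of a thousand
individuals costs on the order of an hour on a cluster, and full optimizations
run for hundreds of generations — which makes *statistical emulation*
attractive: train a fast regression model on simulated input→feature pairs and
let it replace or screen most simulator calls.

`neuremu` implements that whole loop in a self-contained, desk-scale form, for
researchers who want to study, test or teach emulation strategies for neural
simulators without a cluster:

- **Stand-in simulator** — a deterministic adaptive-exponential
  integrate-and-fire neuron (12 mechanistic parameters padded with inert
  dimensions to d = 31) with millisecond cost, plus feature extraction with
  *structural missingness*: a feature whose defining event never happened
  (e.g. the minimum voltage between spikes when fewer than two spikes
  occurred) has no value, and is reported missing rather than imputed.
- **Emulator zoo under one contract** — Gaussian-process regression with the
  ARD squared-exponential kernel
  `k(x,x') = σ_f² exp(−½ Σ_j (x_j−x'_j)²/l_j²)` and profiled-trend marginal
  likelihood (analytic gradients, compiled core); its limiting-linear-model
  variant GPllm (per-dimension data-driven choice of linear trend vs kernel);
  local approximate GP; a greedy treed model with linear/GP leaves; random
  forest, neural network and linear baselines. Every fitted emulator predicts
  `mean, sd, q05, q95`.
- **Scoring and GA** — the summed feature score
  `Global score = Σ_j |f_j,sim − μ_j,exp| / σ_j,exp` (lower is better) and a
  real-coded GA with four execution strategies: full simulation; per-generation
  80/20 split (simulate 80%, emulate 20%); whole-generation emulation with
  periodic refresh and drift checks; and emulator screening of offspring.
- **Missing-feature pipeline** — a random-forest classifier predicts whether a
  feature will be observed; an emulator trained on observed rows predicts its
  value for rows classified observed; confusion-matrix metrics (accuracy,
  sensitivity, specificity) and Gini variable importance summarize the
  classifier.
- **Emulator-based inference** — predictive-interval coverage against a
  nominal 90% level, and Monte-Carlo Sobol sensitivity indices (Saltelli
  pairing, Jansen estimators) with two standard-normal noise factors as
  negative controls, plus main-effect curves.

## Worked example

```r
library(neuremu)

## a GA-like generation: 400 individuals, 31 parameters (19 inert)
syn <- make_synthetic(n = 400, d = 31, seed = 1)
missing_counts(syn$features)[c("IDRest_7.AP_amplitude",
                               "IDRest_7.min_voltage_between_spikes")]
#>               IDRest_7.AP_amplitude IDRest_7.min_voltage_between_spikes
#>                                  61                                  98

## emulate a smooth subthreshold feature and check accuracy
y  <- syn$features$IVf_3.steady_state_voltage_stimend
te <- 321:400
fit <- gp_fit(syn$params[-te, ], y[-te], space = syn$space, seed = 1)
pr  <- predict(fit, syn$params[te, ])
sqrt(mean((pr$mean - y[te])^2)) / sd(y[te])
#> [1] 0.0834018            # RMSE well below half the feature SD

## two-stage pipeline for a structurally missing feature
ymv <- syn$features$IDRest_7.min_voltage_between_spikes
ts  <- fit_two_stage(syn$params[-te, ], ymv[-te],
                     clf = forest_config(500, 6),
                     reg = emulator_spec("gp", n_starts = 1), seed = 1)
prm <- predict(ts, syn$params[te, ])
metrics(confusion_matrix(prm$predicted_missing, is.na(ymv[te])))
#> accuracy 90.0%, sensitivity 96.8%, specificity 66.7%
```

The feature table reports `NA` for every feature whose defining event did not
occur; `metrics()` follows the field's convention that *sensitivity* is the
fraction of truly observed rows predicted observed (the costly error is
discarding valid individuals), and *specificity* the fraction of truly missing
rows predicted missing.

A surrogate-assisted optimization run:

```r
sp  <- default_parameter_space(31)
ref <- sample_population(sp, 1, seed = 9)[1, ]     # "true" individual
tg  <- targets_from_params(ref)                    # its features as targets
run <- run_moo(sp, tg, ga_config(pop_size = 200, generations = 20, seed = 1),
               strategy_config("split", train_frac = 0.8),
               emulator_specs = list(emulator_spec("gp", n_starts = 1)),
               seed = 1)
run
#> moo_run (split): 20 generations, best score 0.7031
#>   simulator calls 3200, emulator predictions 800
```

Exactly 80% of each generation is simulated and 20% emulated, per the split
strategy's accounting.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/neuremu`:

```sh
inst/cli/neuremu make-synthetic --n 1000 --d 31 --seed 7 --out-prefix gen1
inst/cli/neuremu two-stage --train-csv gen1.csv \
    --feature IDRest_7.min_voltage_between_spikes --reg-method gpllm --seed 7
```

Every run writes a JSON manifest (config, seeds, versions, call counts) next
to its outputs.

## Vignette

`vignettes/emulation-methods.Rmd` documents the model and its assumptions, the
synthetic study conditions, numerical choices and known limitations.
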