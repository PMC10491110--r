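# filmsens

Conditional drug-sensitivity modeling in R: a feature-wise linear modulation
(FiLM) network that predicts cellular viability from a transcriptome, a
compound fingerprint, and a concentration, followed by the full downstream
pharmacology — quality-controlled log-logistic dose-response fitting,
integrated-gradients attribution at the predicted IC50, and
mechanism-of-action interpretation statistics. A seeded synthetic benchmark
with planted ground truth makes every stage testable end to end on one CPU.

## Who this is for

Computational pharmacologists and method developers who want a transparent,
fully scriptable implementation of conditional viability modeling: train the
model on a (cell line x gene) expression matrix plus a long viability table,
predict dose-response curves for new lines, and interrogate *why* the model
calls a line sensitive through gene-level attributions and network
statistics.

## The model

Viability is modeled as `y = f(x | n)`:

- `x` — z-scored expression over the training genes,
- `n` — a 513-length compound feature vector: 512 Morgan fingerprint bits
  (radius 2) plus the concentration,
- `f` — an expression encoder producing an embedding `h` of length `g`, a
  compound encoder, and a FiLM generator emitting per-layer `(γ, β)` so each
  FiLM layer applies `h ← γ ⊙ h + β` followed by a linear block (linear,
  ReLU, batch normalization, dropout), then a trunk mapping to one value.

Baseline variants isolate the conditioning mechanism: `scale` (β ≡ 0),
`shift` (γ ≡ 1), `concatenation` (no conditioning; inputs joined before one
trunk), and a *straw* control trained on random fingerprints that ablate
chemical structure. Trained curves over the default grid (32 geometric
concentrations, 1e-3–300 µM) pass a QC cascade (recursive 0.2-rise pruning,
16-point minimum, 0.4 no-response floor) and an LL4 → LL3 → LL2 log-logistic
fitting cascade, yielding absolute IC50 (`e·((d−0.5)/(0.5−c))^(1/b)`),
EC50, per-drug scaled AUC, and delta-method ED50 potency comparisons.
Attributions are integrated gradients from zero baselines at each pair's
predicted IC50, z-score adjusted within each cell line, with
random-initialization and permuted-label control models for soundness.

## Worked example

```r
library(filmsens)
sim <- simulate(simulation_config(seed = 1))          # planted ground truth
fit <- train_benchmark(sim$dataset, variant = "film", seed = 1,
                       options = list(epochs = 10))
fit$state
#> <filmsens_model> variant=film genes=200 g=64 c=32 film_layers=2 trunk=(64,32)
fit$history$max_val_r2
#> 0.702                                  # R2 on held-out cell lines, epoch 10

preds <- predict_response_grid(fit$state, fit$design$expr_z, fit$design$fpmat,
                               lines = sim$dataset$heldout_lines[1],
                               compounds = c("CPD01", "CPD02"))
pharmacodynamics(preds)[, c("compound_id", "family", "b", "d", "e", "ic50",
                            "qc_status")]
#>   compound_id family     b     d     e  ic50 qc_status
#> 1       CPD01    LL4 0.889 1.008 0.236 0.264        ok
#> 2       CPD02    LL4 0.862 0.996 0.335 0.359        ok

true_ic50(sim$truth, sim$dataset$heldout_lines[1], "CPD01")
#> 0.268                                  # uM; the model predicted 0.264
```

The fitted curve for the first held-out line crosses 50% viability at
0.264 µM against a planted truth of 0.268 µM — the model has recovered this
pair's sensitivity from expression and fingerprint alone, on a line it never
saw. Longer training (the 30-epoch benchmark default) raises held-out R² to
~0.83 and the Spearman correlation between predicted and true log10 IC50
across all held-out pairs to ~0.63.

A pipeline front-end chains the stages from one YAML config:

```sh
Rscript inst/cli/filmsens all --config pipeline.yaml --seed 7 -v
```

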