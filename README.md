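# balansite

Two-way rebalancing for heavily imbalanced protein-modification-site
prediction, in R.

## The problem

Protein carbonylation — an irreversible oxidative modification of K, R, T
and P side chains — is typical of residue-level prediction problems where
confirmed modified sites are rare and candidate unmodified sites are
abundant. At imbalance ratios (IR) of 100 or more, an off-the-shelf
classifier predicts "unmodified" everywhere. `balansite` rebalances such
data from both sides at once and classifies with a Gaussian-kernel SVM:

* **Optimal sampling scale.** With `m` positives and `M` negatives, both
  classes are resampled to the common size `s* = sqrt(mM)` — the minimiser
  of the combined cost `s/m + M/s` of oversampling and undersampling
  (`optimal_scale()`).
* **Attention-based undersampling.** Negatives are scored by the diagonal
  of a row-softmax cosine self-attention matrix: stage 1 keeps the
  `(s+M)/2` most representative negatives (smallest self-attention), stage
  2 re-scores them jointly with the positives and keeps the `s` least
  positive-like (largest self-attention) (`attention_undersample()`).
* **GAN-based oversampling.** A small multilayer-perceptron GAN, trained
  on the minority class with seeded, reproducible updates, synthesises the
  `s − m` missing positives (`train_gan()`, `gan_oversample()`).
* **Features and classifier.** Peptide windows (length 21, padded with
  `X`) are encoded as distance-based residue (DR) counts — 20 residue
  counts plus 400 ordered-pair counts per distance `k ≤ d_max`
  (`dr_features()`) — min-max scaled, and classified by an RBF-kernel SVM
  with pairwise-rank AUC / sensitivity / specificity evaluation and
  stratified cross-validation (`train_svm()`, `evaluate()`,
  `cross_validate()`).
* **Baselines and benchmarks.** Random undersampling and SMOTE
  interpolation, seeded synthetic generators for imbalanced feature clouds
  and motif-biased peptide windows, and sweep drivers over imbalance
  ratios and sampling scales (`run_ir_sweep()`, `run_scale_sweep()`).

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, so results drop straight into dplyr/ggplot2
workflows.

## Worked example

```r
library(balansite)

# A synthetic benchmark at IR = 100: 1000 background windows, 10 windows
# carrying a compositional motif, plus a balanced held-out test set.
train <- make_peptide_dataset(n_neg = 1000, n_pos = 10, motif_bias = 0.5, seed = 1)
test  <- make_peptide_dataset(n_neg = 500, n_pos = 500, motif_bias = 0.5, seed = 501)

fit <- fit_evaluate(dr_features(train), dr_features(test),
                    strategy = "attention_gan", seed = 1)
fit$plan
#> <rebalance_plan> m = 10 positives, M = 1000 negatives, scale s = 100
#>   stage 1 keeps 550 negatives; final keep 100; synthesize 90 positives
fit$report
#> <eval_report> Sen = 0.000  Spe = 1.000  AUC = 0.647  (P = 500, N = 500)
```

The plan says the 1000 negatives were reduced to `s = sqrt(10 * 1000) = 100`
in two attention stages and 90 synthetic positives were generated to meet
them. On this fixture the rebalanced model ranks held-out positives above
negatives clearly better than chance (AUC 0.647 from 10 real positives),
while thresholded sensitivity at 0 shows how hard IR = 100 remains —
the gain is in the ranking, not the calls. Compare strategies under
identical seeds with `run_ir_sweep()`, and trace AUC against the sampling
scale with `run_scale_sweep()` (the dashed line in its `autoplot()` marks
`sqrt(mM)`).

A thin command-line wrapper with `simulate`, `features`, `run` and `sweep`
subcommands is installed at `inst/cli/balansite.R`.

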