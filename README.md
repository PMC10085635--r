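# gemgrn

Supervised gene regulatory network (GRN) inference from single-cell
RNA-seq, for computational biologists who have an expression matrix, a
partial ground-truth network (e.g. from ChIP-seq), and want to score
unseen regulator–target pairs — including the *direction* of regulation —
with a classifier whose decisions can be traced back to specific spans of
cells.

## The method

Each labelled gene pair $(i, j)$ is encoded as a **gene expression
motif**: the two expression vectors over $k$ ordered cells are cut into
$L = \lceil k/s \rceil$ aligned windows of $s$ cells and concatenated
position-wise,

$$X_{ij,m} = \big(X_{i,(m-1)s+1..ms},\; X_{j,(m-1)s+1..ms}\big) \in \mathbb{R}^{2s},
\qquad m = 1, \dots, L,$$

so that phase-restricted co-expression — a target tracking its
transcription factor (TF) only during part of a pseudo-time trajectory —
stays visible at its position instead of being averaged away. The motif
sequence passes through a single transformer encoder layer (sinusoidal
positional encoding; two-head scaled dot-product self-attention,
$\mathrm{softmax}(QK^\top/\sqrt{d_h})V$; residual connections with layer
normalization; a position-wise ReLU feed-forward network), is averaged
over positions, and a two-layer sigmoid head returns
$\Pr(\text{interaction})$. Weights are trained with Adam on binary
cross-entropy; backpropagation, the optimizer and the encoder are
implemented in base R and verified against finite differences and
brute-force oracles in the test suite.

The package covers the full protocol around the model:

* **Data**: delimited expression matrices and edge lists, the
  10%-of-cells gene filter, highly-variable-gene selection
  (`read_expression_matrix()`, `filter_genes()`, `select_hvg()`).
* **Tasks**: unbalanced TF-anchored reconstruction, balanced interaction,
  and balanced direction-of-regulation samples
  (`build_gene_gene_samples()`, `build_interaction_samples()`,
  `build_causality_samples()`).
* **Protocols**: stratified 3:1:1 splits (`split_gene_gene()`) and
  TF-disjoint 3-fold cross-validation in which all samples of a regulator
  are held out together (`make_tf_folds()`, `gemgrn_crossval()`).
* **Evaluation**: ROC/PR curves, AUROC (trapezoid), AUPRC (step-wise),
  per-regulator summaries (`roc_pr_curves()`, `per_tf_summary()`).
* **Interpretation**: per-sub-vector classification probabilities and
  most-important-window tallies (`subvector_probabilities()`,
  `tf_importance_tally()`).
* **Synthetic data**: an scRNA-seq-like generator with planted TF→target
  edges synchronized over known cell spans (`simulate_dataset()`,
  `make_task_fixture()`), so everything above is testable without
  external downloads.

## Worked example

Simulate a small pseudo-time data set with four TFs whose 25 targets each
track them over a hidden span of cells, train on the balanced interaction
task, and evaluate on held-out pairs:

```r
library(gemgrn)

spec <- simulation_spec(n_tfs = 4, targets_per_tf = 25, n_noise_genes = 40,
                        k_cells = 300, coupling = 0.9, dropout_rate = 0.2,
                        seed = 42)
fx <- make_task_fixture(spec, "interaction")
fx$expr
#> expression_matrix: 144 genes x 300 cells (pseudotime cell order)

fit <- gemgrn(split_part(fx$samples, fx$split, "train"), fx$expr,
              val_samples = split_part(fx$samples, fx$split, "val"),
              window = 50, epochs = 30, seed = 42)
fit
#> gemgrn: gene-pair transformer classifier
#>   task: interaction, trained on 120 samples (300 cells, window 50, L = 6)
#>   d_model 100 | 2 head(s) | d_ff 200 | dropout 0.50 | lr 0.001
#>   30 epoch(s); best checkpoint at epoch 21 (val AUROC 0.895)

test <- split_part(fx$samples, fx$split, "test")
roc_pr_curves(test$label, predict(fit, test, fx$expr))
#> eval_result: 20 positives / 20 negatives
#>   AUROC 0.8650 | AUPRC 0.8873 (prevalence 0.5000)
```

The held-out AUROC of 0.865 says the model ranks unseen truly regulated
pairs above matched non-regulated pairs 86% of the time; AUPRC 0.887
against a 0.5 prevalence quantifies the same ranking from the precision
side. Asking *which cells* the classifier relies on:

```r
tf_importance_tally(fit, fx$samples[fx$samples$label == 1, ], fx$expr)
#>   position count fraction
#> 1        1    14     0.14
#> 2        2     3     0.03
#> 3        3    33     0.33
#> 4        4    22     0.22
#> 5        5    22     0.22
#> 6        6     6     0.06
```

Each positive pair's most influential 50-cell window is tallied; here the
mass concentrates on the middle of the trajectory, where the generator
planted the synchrony spans.

A command-line front end wrapping the same functions (simulate / train /
evaluate / interpret / crossval subcommands, one immutable run directory
with a manifest per invocation) is installed at `inst/cli/gemgrn.R`.

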