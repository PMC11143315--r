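---
title: "Patient-similarity networks and GNN triage classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-similarity networks and GNN triage classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`trisimnet` implements a decision-support pipeline for emergency-department
triage. A tabular patient cohort is preprocessed into a numeric feature
matrix, converted into a *patient-similarity network* — each patient a node,
each edge a pair of patients whose feature vectors pass a similarity
threshold — and a graph neural network (GNN) is trained to assign each node
one of four triage severity codes (from "needs immediate attention" down to
"minor urgency"). The premise is that patients in similar physiological
states should receive similar severity codes, so a classifier that can see a
patient's neighbourhood in feature space, not just the patient's own record,
has more evidence to work with.

This vignette documents the modelling choices, the tunable parameters, and
the limits of what the bundled synthetic-data experiments can show.

## Preprocessing workflow

`preprocess_cohort()` applies five steps in a fixed order:

1. **Duplicate and null removal** — exact duplicate rows are dropped (first
   occurrence kept); rows with a missing severity label are dropped (they
   cannot supervise training); rows missing a schema-mandatory demographic
   field (gender in the bundled admission schema) are dropped. Each count is
   recorded in the provenance log, and the counts always satisfy
   `rows_in = rows_out + duplicates + missing_label + missing_mandatory`.
2. **Mode imputation** — remaining missing cells are replaced by the most
   frequent observed value of their column. The mode can tie; ties are broken
   toward the smallest value under the column's natural ordering. Any
   deterministic rule would do; smallest-value is reproducible and easy to
   reason about.
3. **Label encoding** — categorical columns (declared by the schema) are
   mapped to integers by lexicographic order of the observed values, and the
   maps are kept so the encoding is invertible.
4. **Class balancing** — triage labels are heavily imbalanced in practice,
   so SMOTE oversampling equalizes class counts: each synthetic minority row
   is `x_i + u (x_nn - x_i)` with `u ~ U(0,1)` and `x_nn` one of the
   `k = 5` nearest same-class neighbours (Euclidean). `k = 5` is the
   canonical SMOTE default. A combined variant
   (`balance_config("smote_undersample")`) oversamples up to and
   undersamples down to the median class size, for cohorts where the
   majority class is too dominant to clone up to.
5. **Min-max scaling** — every column is mapped to `[0, 1]`; constant
   columns map to 0 (the convention avoids 0/0).

Balancing **precedes** scaling and graph construction, which mirrors the
workflow this pipeline models. Because synthetic minority rows therefore
exist before the train/test split, information can leak from training
interpolants into test neighbourhoods; `run_experiment(leakage_safe = TRUE)`
instead splits first and balances the training rows only. The default
remains the workflow-faithful (optimistic) order, and the option is the
honest-evaluation alternative.

## Similarity graphs

Four metrics are supported: cosine similarity, and Euclidean, Manhattan and
Minkowski (order `p`) distances, with
`minkowski(p=1) = manhattan` and `minkowski(p=2) = euclidean` exactly. An
edge connects two patients when the metric value passes the threshold
*strictly* — `value > θ` for cosine, `value < θ` for distances; float ties
are measure-zero, so the strictness convention is immaterial in practice but
is applied literally. Edge weights store the raw cosine similarity or
`1/(1+d)` for distances; message passing ignores them by default
(`use_edge_weights = TRUE` propagates them through the degree-normalized
operators) because the GNN layer definitions modelled here do not specify
weighted aggregation.

Pairwise values are computed in row blocks (`block_size` rows at a time)
with edges emitted from the upper triangle only, so memory stays
`O(block × n)`; `threshold_sweep()` reuses one pairwise pass across a whole
threshold grid. Nestedness is a theorem under this construction — raising a
similarity threshold can only remove edges — and the test suite asserts it,
along with the `L_p` ordering (Minkowski values non-increasing in `p`).

## GNN architectures

All models end in a C-dimensional logit layer trained with softmax
cross-entropy; ReLU follows every non-final layer; dropout rate is 0.2.

* **gcn5** — five graph-convolution layers (degree-normalized mean
  aggregation, `D^{-1/2}(A+I)D^{-1/2}`), dimensions
  (F,64),(64,64),(64,64),(64,64),(64,C), dropout after layers 2–4.
* **gcn4** — four layers with hidden width 32, dropout after layers 2–3
  (the placement mirrors gcn5's "after each interior hidden layer" policy).
* **gatv2** — two GATv2 attention layers: (F, 8)×4 heads concatenated to
  32, then (32, C); LeakyReLU slope 0.2 inside the attention score; one
  dropout before each layer.
* **sage5** — five GraphSAGE layers, widths 64, 32, 16, 8, then C;
  max-pool aggregation except the third layer (mean); dropout after the
  fourth layer. The max-pool aggregator applies a learned linear projection
  and ReLU *before* the elementwise max, the original GraphSAGE pooling
  aggregator. The projection matters: a raw-feature max over the hundreds
  of neighbours a dense similarity graph produces is nearly identical for
  every node, which starves the layer of gradient signal; the learned
  projection keeps the pooled representation node-specific.

Forward and backward passes are exact analytic implementations (verified
against finite differences to `1e-6` in the test suite), with Rcpp kernels
for the max-pool scatter/gather and the per-edge attention softmax
segments. Inference mode disables dropout and is deterministic; all message
passing is permutation-equivariant by construction, which the tests assert.

## Training

Adam with weight decay `5e-4`; learning rate `0.01` (`0.005` for gatv2);
cross-entropy on the training-mask logits. Gradients are clipped to global
L2 norm 1 before each step — the very first Adam steps are otherwise
sign-steps of size `lr` in every coordinate, which can throw the deep
narrow pyramid into a uniform-prediction plateau it escapes only slowly.
Clipping is a numerical safeguard; it does not alter converged behaviour.

GraphSAGE-family models train on neighbor-sampled mini-batches: training
nodes are partitioned into batches of `batch_size` (3000 by default) seed
nodes, and each batch's subgraph samples at most `fanout = 10` neighbours
per node per hop for one hop per layer. Each training node seeds exactly
one batch per epoch, and batches are resampled every epoch from the seeded
RNG stream, so training is bit-reproducible. Note the step-count
consequence at small cohort sizes: with fewer than 3000 training nodes
there is a single batch — one optimizer step — per epoch, so reaching the
same optimizer-step budget as a large-cohort run requires proportionally
more epochs (the package's end-to-end tests use 250 epochs at n ≈ 2500 for
this reason; at the 15000-node scale the same budget is ~50 epochs of 5
batches).

Default epochs are 100 for neighbor-sampled GraphSAGE and 200 full-graph
for the other families, with patience-20 early stopping on validation
accuracy (the best-validation parameters are restored). `eval_every`
controls how often the full-graph evaluation (and the early-stopping check)
runs; on dense graphs the evaluation forward pass dominates wall time, so
sparse evaluation is the main speed lever.

## Splits and evaluation

`make_split()` mirrors the tabular protocol: 30% of labeled nodes to the
test pool, then 30% of that pool to validation, the rest to training —
stratified by class via largest-remainder apportionment (per-class
proportions within one unit across masks) and deterministic under its seed.
Accuracy is the primary metric; reports also carry the confusion matrix,
per-class precision/recall and macro-F1 as supplementary output.

`sensitivity_analysis()` crosses metrics × thresholds × architectures on a
shared prepared cohort and split seed and tabulates test accuracy next to
the SVM (RBF kernel, default regularization) and KNN (`k = 5`) tabular
baselines — both unspecified in the modelled setup beyond their family, so
library defaults are used and exposed. `ablation_study()` refits the
GraphSAGE base and eight variants (remove layer 2, 3, 4, or all three ×
hidden width 8 or 64). A variant keeps the surviving layers' aggregators
and sets every remaining hidden dimension to the chosen width, re-chaining
adjacent dimensions (removing all three middle layers leaves F → width →
C). With uniform re-chaining a width-64 single-removal variant can carry
*more* parameters than the 64-32-16-8 pyramid base; parameter counts are
reported per variant so the comparison is explicit.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the pipeline needs without any
external data: numeric features drawn per class from isotropic Gaussians
whose centroids sit `separation` apart (on scaled basis directions, so
exactly C feature columns carry the class signal); categorical features
drawn from per-class tilted multinomials (the preferred level's weight is
`1 + cat_signal`); then exact duplicate rows, missing feature cells (never
in mandatory columns) and missing labels injected at configurable rates
with the bookkeeping returned as ground truth. Two schema profiles match
the cohorts the pipeline targets: a 16-feature admission table
(`kaggle16_profile()`, two categorical features, 4-level triage label) and
a 14-feature ED triage table (`mimic14_profile()`, six categorical
features, 4-level acuity).

Defaults model a realistic triage cohort: imbalanced class mix
(10/18/30/42%), `separation = 4`, unit noise, 1% missing cells, 2% missing
labels, 3% duplicates. What the generator does *not* emulate: realistic
marginal distributions, correlated vitals, label noise, or informative
missingness. Passing tests on these cohorts therefore demonstrates that the
machinery is correct and that the pipeline recovers plantable structure —
not that any particular accuracy will transfer to real triage data.

Study-condition sizes used in the deeper tests: the end-to-end recovery
check uses n = 1500, `separation = 6`, cosine threshold 0.9 and a 5-seed
median; the sampler contract is exercised on a 15000-node sparse graph
(batch 3000 → 5 batches); the ablation harness runs reduced 10-epoch fits
on an n = 400 cohort.

## Numerical and design notes

* Cosine rejects zero-norm rows explicitly (they have no direction); on
  min-max-scaled data a zero-norm row is an all-minimum patient, which the
  error message names.
* Mode/tie, constant-column and argmax tie conventions are all "smallest
  index wins", making every path deterministic.
* The split apportionment guarantees the printed 700/300/90 sizes at
  n = 1000.
* Model checkpointing is plain R serialization of the fit object; the
  architecture table (`architecture()`) embeds the structural spec.
* A command-line wrapper is intentionally absent: the exported functions
  and `scripts/acceptance.R` are the interface; every pipeline stage is a
  single function call.

## Known limitations

* Training the GATv2 model on very dense graphs is memory-hungry (per-edge
  attention caches); keep cohorts in the low thousands of nodes or raise
  the threshold.
* The neighbor sampler treats sampled edges as undirected within the batch
  subgraph — a slight densification relative to a strictly directed
  sampling tree.
* SMOTE-before-split remains the default for workflow fidelity despite its
  leakage optimism; use `leakage_safe = TRUE` for honest generalization
  estimates.
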