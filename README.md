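# trisimnet

Patient-similarity networks and graph neural networks for emergency-department
triage severity prediction.

## The problem

Emergency departments assign each arriving patient a triage severity code —
four levels here, from *needs immediate attention* down to *minor urgency* —
from demographics, vitals and biochemistry. `trisimnet` implements a
network-medicine approach to automating that assignment: patients become
nodes of a **patient-similarity network**, with an edge between two patients
whenever the similarity of their feature vectors passes a threshold

- cosine similarity: edge iff `cos(x_i, x_j) > θ`
- Euclidean / Manhattan / Minkowski-`p` distance: edge iff `d(x_i, x_j) < θ`,
  with `d_p(x, y) = (Σ_k |x_k − y_k|^p)^{1/p}`

and a graph neural network performs 4-class **node classification** over that
network. Three architectures are provided, trained with Adam
(learning rate 0.01, or 0.005 for the attention model; weight decay 5·10⁻⁴)
on softmax cross-entropy:

| family  | structure |
|---------|-----------|
| `gcn5` / `gcn4` | 5 (resp. 4) graph-convolution layers, hidden width 64 (resp. 32), degree-normalized aggregation `D^{-1/2}(A+I)D^{-1/2}` |
| `gatv2` | 2 GATv2 attention layers, 8 hidden units × 4 heads, then C outputs |
| `sage5` | 5 GraphSAGE layers (64, 32, 16, 8, C), max-pool aggregation except mean at layer 3, neighbor-sampled mini-batches (batch 3000, fanout 10) |

Around the classifier sit the full pipeline stages: schema-aware cohort
loading, the preprocessing workflow (duplicate/null removal → mode
imputation → label encoding → SMOTE class balancing → min-max scaling),
threshold sweeps with network statistics (edges, isolated nodes),
sensitivity and layer-ablation studies, SVM/KNN tabular baselines, and a
synthetic-cohort generator with controllable class separation so that every
stage is testable without external data. Who this is for: clinical
informatics researchers studying graph-based triage models, and anyone who
needs a self-contained, deterministic reference implementation of the
tabular-to-graph node-classification pipeline.

## Worked example

```r
library(trisimnet)

gen <- generate_cohort(cohort_spec(n = 600, separation = 6, seed = 1))
pc  <- preprocess_cohort(gen$cohort)
pc
#> Prepared cohort: 1000 patients x 16 features
#>   classes: Green, Orange, Red, Yellow
#>   class counts: 250 / 250 / 250 / 250
#>   - drop_duplicates_and_nulls rows_in=618 duplicates_removed=18 missing_label_removed=12 missing_mandatory_removed=0 rows_out=588
#>   - impute_mode cells_filled=90
#>   - encode_categoricals columns=3
#>   - balance_classes method=smote rows_in=588 rows_out=1000
#>   - minmax_scale columns=16

g <- build_graph(pc, metric_spec("cosine", threshold = 0.9))
g
#> Patient-similarity network: 1000 nodes, 101670 edges, 0 isolated
#>   metric: cosine   threshold: 0.9

fit <- triage_gnn(g, "sage5", epochs = 250, seed = 1,
                  eval_every = 25, patience = Inf)
fit
#> GNN triage classifier (sage5)
#>   graph: 1000 nodes, 101670 edges
#>   epochs run: 250  final loss: 0.3104
#>   accuracy  train: 0.9143  validation: 0.9333  test: 0.9286
```

The preprocessing log shows the generator's injected defects being cleaned
(18 duplicates, 12 missing labels), SMOTE bringing the imbalanced classes to
250 each, and scaling to `[0,1]`. The fitted GraphSAGE classifier reaches
92.9% held-out test accuracy on this well-separated synthetic cohort (the
separation parameter plants genuine class structure; accuracy on real triage
data depends on the data). A threshold sweep reproduces the familiar
network-statistics trade-off — stricter thresholds isolate patients, looser
ones densify the graph:

```r
threshold_sweep(pc, "cosine", c(0.98, 0.95, 0.90))
#>   metric  p threshold n_nodes n_edges n_isolated
#> 1 cosine NA      0.98    1000    1682        296
#> 2 cosine NA      0.95    1000   18437         23
#> 3 cosine NA      0.90    1000  101670          0
```

and `tabular_baselines(pc, seed = 1)` trains the SVM/KNN comparison line on
the same features and split (SVM 1.00, KNN 0.98 here — on this geometry the
tabular features are themselves highly separable).

`sensitivity_analysis()`, `ablation_study()`, `write_graphml()` /
`write_edgelist()` and `predict()` on extended graphs (new patients are
classified inductively, without retraining) cover the remaining workflows;
see the methods vignette in `vignettes/`.

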