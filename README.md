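# spatialcci

Inference of spatially resolved cell–cell communication from spatial
transcriptomics by multimodal graph attention.

## What problem this solves, and for whom

Spatial transcriptomics assays (HDST, 10X Visium, and kin) measure gene
expression together with each cell's or spot's 2-D tissue position, and
usually an aligned H&E image. For researchers studying tissue
microenvironments, a central question is *which cells communicate*.
Ligand–receptor co-expression methods answer at cell-type level and
depend on incomplete prior databases; sparse, noisy spatial counts make
them fragile. `spatialcci` takes the complementary, annotation-free
route: it treats communication inference as **link prediction on the
spatial contact graph**, learning from the data which pairs of cells
"belong together", then using the learned pairwise probabilities to
recover missed contacts and to propose **distal** (non-contact)
interactions at single-cell resolution.

## The model

* **Contact graph.** Each cell is connected to its $k = 5$ nearest
  neighbours (symmetrized); these edges are the positive training set,
  split 70/15/15 into train/validation/test with 1:1 uniformly sampled
  non-edge negatives per split.
* **Dual-stream GAT encoder.** Two independently parameterised two-layer
  graph attention networks run on the same graph — one with normalized
  log expression as node features, one with local image-patch features.
  Per head: $e_{ij} = \mathrm{LeakyReLU}(a^\top[Wh_i \| Wh_j])$,
  $\alpha_{ij} = \mathrm{softmax}_{j\in N(i)}(e_{ij})$,
  $h'_i = \mathrm{ELU}\left(\sum_{j\in N(i)} \alpha_{ij} W h_j\right)$;
  4 heads concatenated in layer 1, averaged in layer 2.
* **Fusion + decoder.** An MLP reduces the concatenated stream embeddings
  to $Z$ (n x 32); the inner-product decoder
  $A' = \sigma(ZZ^\top)$ scores every cell pair with an edge
  probability.
* **Loss.** $L = \alpha\,L_{reg} + \beta\,L_{count} + \gamma\,L_{feature}$:
  balanced binary cross-entropy on train edges vs negatives, plus MSE
  reconstruction of each stream's input features ($\gamma = 0$ when the
  image is ablated).
* **Protocol.** Adam (single-cell resolution) or SGD (spot resolution) at
  lr $10^{-2}$; reduce-on-plateau (patience 10, factor 0.05) on
  validation loss; checkpoint at best validation AUC; metrics: AUC-ROC,
  accuracy, F1, AUC-PRC, average precision.

The package also implements the surrounding experiment matrix: false-edge
injection for noise-robustness analysis, image-feature ablation,
communication-strength summaries between cells and cell types, and a
synthetic spatial-data generator so everything runs offline.

## Worked example

```r
library(spatialcci)

cfg <- run_config(seed = 0, epochs = 300)   # simulates 300 cells x 200 genes, 4 types
res <- run_pipeline(cfg, out_dir = "run0")

res$metrics
#> <metrics_report> AUC-ROC 0.942  ACC 0.754  F1 0.802  AUC-PRC 0.938  AP 0.938  (140 pos / 140 neg)
res$trained
#> <trained_model> 300 epochs, best val AUC 0.9567 at epoch 187
res$communication$type_by_type_counts
#>       type1 type2 type3 type4
#> type1  1996  2436  1513  2424
#> type2  2436  2490  1522  1539
#> type3  1513  1522  2167  3225
#> type4  2424  1539  3225  1732
```

Reading the output: of the 140 held-out contact edges scored against 140
matched non-edges, the decoder ranks them with AUC-ROC 0.942 — the model
recovers true contacts it never saw from expression + image structure
alone. `res$predicted` holds every pair called at probability ≥ 0.5,
`res$distal` the called pairs that are *not* spatial contacts and are
longer than the 95th percentile of contact-edge lengths, and the counts
matrix tallies called interactions by cell-type pair. `run0/` contains
the edge list, metrics JSON, embeddings, predicted adjacency, training
history and a hashed manifest.

Robustness to a corrupted training graph:

```r
run_robustness(run_config(seed = 0, epochs = 300), fractions = c(0.1, 0.3, 0.5))
# one trained model per injection fraction; columns include the
# noise-discrimination AUC (true train edges vs injected false edges)
```

A thin CLI over the same functions lives at
`inst/scripts/spatialcci-cli.R` (subcommands `simulate`, `run`,
`robustness`).

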