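# clusternet

Graph-based classification of 2D single-molecule localization microscopy
(SMLM) point clouds from their **supracluster structure** — the spatial
arrangement of clusters of localizations across a region of interest (ROI),
not just the shape of any one cluster.

The package is aimed at microscopists and image analysts working with
DNA-PAINT / dSTORM style localization tables (x, y in nm, optionally frame,
photon count, PSF fit quality, precision) who want to classify ROIs or
annotated cells by their nanoscale organization, and to understand *why* the
classifier decides as it does.

## What it does

1. **Preprocess** (`filter_localizations`, `temporal_group`, `assign_cells`,
   `filter_cells`): quality filters (photons ≤ 30 000, PSF σ in 75–200 nm,
   p ≤ 0.01, precision ≤ 25 nm), blinking-event grouping (60 nm, ≤ 2 frame
   gap, ≤ 5 frame lifetime), per-cell extraction with membrane/interior
   labels.
2. **Cluster** (`cluster`): seeded k-means (k-means++, default k = 12) or
   DBSCAN; clusters with ≤ 2 localizations are discarded.
3. **Featurize** (`compute_features`, `cluster_features`): eight handcrafted
   features per cluster — count, radius of gyration squared, convex-hull
   perimeter, linearity (λ₀−λ₁)/λ₀, planarity λ₁/λ₀, length 2.35√λ₀, area
   2.35²√(λ₀λ₁), density count/area — with λ₀ ≥ λ₁ the principal-component
   variances of the member positions.
4. **Graph** (`build_graph`): localization nodes + cluster nodes (centroids),
   undirected edges to each node's five nearest neighbours plus a self-loop;
   positions normalized to [−1, 1] per graph, features min–max scaled to
   [0, 1] with training-set statistics.
5. **Classify** (`clusternet_init`, `train`, `evaluate`): *ClusterNet*, four
   PointTransformer-style vector-attention message passing layers over the
   cluster graph, global max pooling and a linear log-softmax readout.
   *ClusterNet-HCF* uses the handcrafted features; *ClusterNet-LCF* learns
   8-dim cluster embeddings from raw member positions with *LocNet*, trained
   end-to-end. Training: Adam (lr 0.001, weight decay 0.0001), NLL loss,
   inverse-class-frequency weighted sampling, random in-plane rotation
   augmentation, validation-best checkpointing.
6. **Explain** (`extract_features`, `umap_embed`, `fidelity`,
   `subgraphx_search`): layer-wise feature UMAPs; positive/negative fidelity
   (Fid+ = necessity, Fid− = sufficiency of a subgraph for the predicted
   class); SubgraphX-style Monte-Carlo tree search with Shapley scoring for
   the most important connected subgraph (≤ 8 nodes, 100 rollouts).
7. **Synthetic data** (`make_default_templates`, `sample_roi`,
   `sample_dataset`): DNA-origami-like layouts (3×4 grid, line, ring, cross on
   a 13 nm pitch) with Poisson site counts, Gaussian spread, uniform
   background and per-site "misfold" dropout — so the whole pipeline is
   testable without downloads.

The neural network and its training loop are implemented natively in R on a
small reverse-mode autodiff engine (`R/autodiff.R`) whose gradients are
verified against finite differences in the test suite.

## Worked example

Train ClusterNet-HCF on a small synthetic dataset and inspect the metrics:

```r
library(clusternet)

lib   <- make_default_templates()                      # grid / line / ring / cross
tabs  <- sample_dataset(lib, 60, simulation_params(seed = 7))
css   <- lapply(tabs, function(tb) cluster(tb, clustering_config(k = 12, seed = 1)))
feats <- lapply(css, cluster_features)
labs  <- vapply(tabs, function(t) t$gt_label, character(1))

sp     <- make_splits(labs, "stratified_cv", seed = 1)[[1]]
fn     <- c("count","rg2","perimeter","linearity","planarity","length","area","density")
scaler <- fit_scaler(do.call(rbind, lapply(feats[sp$train], function(f) as.matrix(f[, fn]))))
graphs <- mapply(function(cs, f) build_graph(cs, scale_features(f, scaler)),
                 css, feats, SIMPLIFY = FALSE)

model <- clusternet_init(model_config(names(lib$classes), mode = "hcf", seed = 1))
model <- train(model, graphs, sp$train, sp$val,
               train_config(epochs = 40, batch_size = 64, seed = 1))
evaluate(model, graphs[sp$test])
```

```
<metrics_report>
  balanced accuracy: 0.9167   macro AUROC: 0.9902
  grid       recall 0.833  AUROC 0.993
  line       recall 0.917  AUROC 0.993
  ring       recall 0.917  AUROC 0.991
  cross      recall 1.000  AUROC 0.984
```

(At the scale of the reference experiment in the test suite — 200 ROIs per
class, 50 epochs — the same model reaches ≈ 0.96 balanced accuracy.)

Balanced accuracy is the arithmetic mean of the per-class recalls; AUROC is
one-vs-rest per class. Explaining one test graph:

```r
res <- subgraphx_search(model, graphs[[sp$test[1]]],
                        explain_config(rollouts = 100, seed = 1))
res$fidelity
#> <fidelity_report> nodes {2,3,4,5,7,8,9,11}: Fid+ 0.5028, Fid- -0.0007677 (class 1)
```

A Fid− near 0 says the returned subgraph alone nearly reproduces the full
graph's predicted-class probability (it is sufficient); a large Fid+ says
removing it destroys the prediction (it is necessary).

The same stages are scriptable from a shell via the thin CLI
(`inst/cli/clusternet.R`): `generate`, `preprocess`, `featurize`, `graphify`,
`train`, `evaluate`, `explain`, `run`, with a YAML config for the full
pipeline (`run_pipeline()`; see the vignette for the schema).

## Graph container format

Graphs are stored as versioned JSON (`write_graph`/`read_graph`): a header
(`format: "clusternet-graph"`, `version: 1`) plus `loc_pos`, `loc_cluster`,
`cluster_pos`, `cluster_features` (+ names), `edges` (undirected pairs,
self-loops included), `label`, `source_id`. Localization tables round-trip
through Apache Parquet (label and source in file metadata) or CSV (label as a
repeated `gt_label` column). Model checkpoints are single-file JSON archives
(`save_model`/`load_model`).
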