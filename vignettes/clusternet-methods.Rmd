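---
title: "Classifying SMLM point clouds from supracluster structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SMLM point clouds from supracluster structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule localization microscopy (SMLM) yields a list of molecule
coordinates with nanometre precision rather than a pixel image. Many biological
questions hinge not on the shape of any single cluster of localizations but on
the *arrangement of multiple clusters* in a region of interest (ROI) — the
supracluster structure. `clusternet` classifies 2D SMLM ROIs (or annotated
cells) from exactly this information: it clusters the localizations, summarizes
each cluster by shape features, represents the ROI as a graph of cluster nodes,
and classifies the graph with a neural network whose message passing is aware
of the cluster geometry.

Two model variants exist. **ClusterNet-HCF** feeds eight handcrafted cluster
features through the graph network. **ClusterNet-LCF** replaces them with an
8-dimensional embedding learned from the raw member localizations by a
point-based module (**LocNet**) trained end-to-end with the classifier.

## Preprocessing

Quality filtering and temporal grouping follow standard dSTORM practice and
are controlled by `quality_thresholds()` and `grouping_params()`:

* localizations with more than 30 000 photons, a fitted PSF standard deviation
  outside 75–200 nm, a PSF fit p-value above 0.01 or a localization precision
  above 25 nm are removed;
* localizations within 60 nm and at most 2 frames apart are chained into one
  blinking-event track; tracks spanning more than 5 frames are removed, the
  rest are replaced by their mean position.

Two details of temporal grouping are genuinely open and configurable choices:
chaining is *transitive* (a track may extend as long as each successive link is
within the radius and frame gap), and the distance is measured to the track's
*most recent member*, not its running mean. The grouped position is the
unweighted mean of the members.

For tissue data, localizations are assigned to annotated cells
(`assign_cells()`, polygons or a label mask) with membrane/interior labels, and
cells with fewer than 500 localizations or fewer than 5 membrane or 5 interior
localizations are dropped (`filter_cells()`).

Each ROI/cell is then partitioned by `cluster()`: seeded k-means (default
k = 12, k-means++ initialization with 10 restarts — initialization is not
otherwise pinned down, and restarts stabilize the partition) or DBSCAN
(ε in nm, minPts; noise points are excluded downstream). Clusters with two or
fewer localizations are discarded so that the convex hull and principal
components are always defined.

## Handcrafted cluster features

For a cluster with member positions $p_i \in \mathbb{R}^2$ (nm), with
$\lambda_0 \ge \lambda_1$ the eigenvalues of the covariance of the members:

| feature | definition | units |
|---|---|---|
| count | number of localizations $n$ | – |
| rg2 | $\frac1n\sum_i \lVert p_i - \bar p\rVert^2$ (radius of gyration squared) | nm² |
| perimeter | convex hull perimeter | nm |
| linearity | $(\lambda_0-\lambda_1)/\lambda_0$ | – |
| planarity | $\lambda_1/\lambda_0$ | – |
| length | $2.35\sqrt{\lambda_0}$ | nm |
| area | $2.35^2\sqrt{\lambda_0\lambda_1}$ | nm² |
| density | count / area | nm⁻² |

The constant 2.35 is the full width at half maximum of a Gaussian in units of
its standard deviation and is used literally (not $2\sqrt{2\ln 2}$). In 2D,
linearity + planarity = 1; both are kept — the redundancy costs nothing and
keeps the feature vector at eight entries. Numerical choices:

* the covariance uses the sample ($n-1$) denominator by default; a `denom`
  switch offers the $1/n$ convention;
* collinear clusters ($\lambda_1 = 0$) have zero area and hence undefined
  density; they are rejected (`compute_features()`) or dropped with a warning
  (`cluster_features()`) rather than given infinite density;
* localizations are not precision-weighted; weighting is a possible extension.

## Graph construction

Each ROI becomes a `hier_graph`: localization nodes (positions only, no
features) attached to their cluster node; cluster nodes at the unweighted
centroid of their members; undirected edges from every cluster node to itself
(self-loop) and its five nearest neighbours. Positions are normalized per
graph, $x \to 2(x - \min x)/\max(\mathrm{xrange}, \mathrm{yrange}) - 1$, the
same divisor for $y$, so the layout fits $[-1,1]^2$ with its aspect ratio
preserved. Cluster features are min–max scaled to $[0,1]$ with statistics
measured *on the training set only* (`fit_scaler()` / `apply_scaler()`);
out-of-range test values are clamped, keeping the model's input domain fixed.

Open choices made here: nearest-neighbour ties break towards the lowest
cluster id (determinism); symmetrization is by union (an undirected edge
exists if either endpoint lists the other); localization→cluster membership is
stored as an index rather than as explicit edges (equivalent information, and
the pooling step consumes the index directly).

## Models

The message passing layer is a PointTransformer-style convolution with vector
attention. For node $i$ with neighbourhood $\mathcal N(i)$ (its undirected
edges, self-loop included), with learned projections $q_i = W_q x_i$,
$k_j = W_k x_j$, $v_j = W_v x_j$ and a two-layer MLP $\delta_{ij} =
\mathrm{MLP}_\delta(p_j - p_i)$ of the relative positions:

$$\alpha_{ij} = \mathrm{softmax}_{j \in \mathcal N(i)}
  \big(\mathrm{MLP}_\gamma(q_i - k_j + \delta_{ij})\big), \qquad
  y_i = W_o \sum_{j \in \mathcal N(i)} \alpha_{ij} \odot (v_j + \delta_{ij})$$

The attention is per-channel (the softmax normalizes each channel over the
neighbourhood), the relative-position encoding enters both the attention
logits and the values — so the layer is translation invariant by construction
— and $W_o$ is an output projection closing the block. ClusterNet applies an
input linear layer ($8 \to$ `hidden_dim`), four such blocks with ReLU and
residual connections, element-wise max pooling over cluster nodes, and a final
linear layer with log-softmax output. LocNet applies an input linear layer on
member positions (centred on the cluster centroid), two blocks over a
k-nearest-neighbour graph among the members, max pooling over members and a
sigmoid output, giving per-cluster features in $(0,1)^8$.

The published architecture fixes the number of message passing layers (4), the
embedding length (8), global max pooling and the log-softmax/NLL objective,
but not the hidden widths or LocNet's internal structure. The package's
defaults — `hidden_dim = 96` for the message passing layers, LocNet with two
blocks, internal width 8 and an 8-neighbour attention neighbourhood — are
therefore documented defaults, and all configurable via `model_config()`. The
width was chosen by a small seed-variance study on the synthetic reference
task (narrower trunks recover the four classes noticeably less reliably);
the LocNet sizes keep single-CPU training in the minutes range. The whole network (including the training loop) is
implemented natively in R on a small reverse-mode autodiff engine; its
gradients are verified against finite differences in the test suite.

## Training and evaluation

`train()` follows the stated procedure: Adam (learning rate 0.001, weight
decay 0.0001), negative log-likelihood on log-probabilities, batch size 128
(8 is more appropriate for small cell datasets), a weighted random sampler
with inverse-class-frequency item weights (equal expected class frequencies),
one uniform random in-plane rotation per sampled graph as augmentation, and
validation after every epoch without augmentation; the checkpoint with the
lowest validation loss is returned. Classification ties break towards the
lowest class index.

`make_splits()` provides stratified 64/16/20% train/validation/test
cross-validation folds, and a grouped mode where a group (e.g. patient) never
spans folds; groups are assigned greedily to balance fold sizes and class
ratios, which matches the stated goal (the assignment algorithm itself is an
open choice). `evaluate()` reports per-class recall, balanced accuracy (their
arithmetic mean), the confusion matrix, and one-vs-rest AUROC per class plus a
macro average.

## Explainability

`extract_features()` exposes four feature levels — handcrafted, LocNet
embeddings, post-message-passing cluster features, and pooled whole-graph
features — normalized per feature by subtracting the mean and dividing by the
variance measured on the non-reserved data. Dividing by the *variance* is the
literal convention adopted here; a `scale = "sd"` flag offers conventional
z-scoring, since the two differ whenever a feature's variance is far from 1.
`umap_embed()` produces the 2D map (20 neighbours, 0.5 minimum distance)
through the umap-learn implementation, seeded for determinism.

`fidelity()` anchors both metrics on the model's *predicted* class for the
full graph: Fid+ is the probability drop when the subgraph is removed
(necessity), Fid− the drop when only the subgraph is kept (sufficiency); best
performance is Fid+ → 1, Fid− → 0. Node removal deletes the node and its
incident edges and keeps the remaining normalized positions as-is —
re-normalizing would confound occlusion with a geometry change.

`subgraphx_search()` runs a Monte-Carlo tree search over connected subsets:
the root is the full node set, actions prune one node while preserving
connectivity, and leaves (≤ 8 nodes by default) are scored by a Monte-Carlo
Shapley estimate of their contribution to the predicted-class probability,
with coalitions drawn from a 2-hop neighbourhood of the candidate set (the
restriction is standard practice; radius and sample count are configurable).
100 rollouts is the default. The tree policy uses an upper-confidence rule
with the child's Shapley estimate as prior (exploration constant 5, a
documented default). On disconnected cluster graphs the search runs per
component. An occluded evaluation of an empty node set returns the uniform
probability 1/`n_classes`.

## Pipeline configuration

`run_pipeline()` drives all stages from one YAML (or list) config; unknown
keys are rejected before any computation and a `seed` is mandatory (no silent
nondeterminism). The schema, with defaults:

```yaml
seed: 1                 # mandatory; master seed for every stage
out: runs/demo          # run directory
input: null             # directory of parquet/csv localization files;
                        # when null, the synthetic generator is used
generate:
  classes: [grid, line, ring, cross]
  n_per_class: 50
  locs_per_site_mean: 30      # Poisson mean per binding site
  site_sigma: 5               # nm
  background_rate: 5          # Poisson mean per ROI
  misfold_prob: 0.05
  rotation: true
  roi_extent: 200             # nm
  site_spacing: 13            # nm
preprocess:
  method: kmeans              # or dbscan
  k: 12
  eps: 50                     # nm (dbscan)
  min_pts: 3                  # (dbscan)
  min_cluster_size: 3
graph:
  n_neighbors: 5
model:
  mode: hcf                   # or lcf
  hidden_dim: 96
  embed_dim: 8
  n_message_layers: 4
  locnet_hidden: 8
  locnet_k: 8
train:
  epochs: 100
  batch_size: 128
  lr: 0.001
  weight_decay: 0.0001
explain:
  enabled: false
  n_graphs: 2
  rollouts: 100
  max_subgraph_nodes: 8
  shapley_samples: 100
```

Every run directory receives exactly one `manifest.json` (config snapshot,
seed, package version, md5 of every output); rerunning the same config
reproduces the outputs.

## Synthetic data

`make_default_templates()` provides four binding-site layouts on a 13 nm
pitch — a 3×4 grid of 12 sites, a 6-site line, an 8-site ring and a 9-site
cross — emulating DNA-origami designs with one structure per 200×200 nm ROI.
`sample_roi()` draws Poisson(`locs_per_site_mean` = 30) localizations per site
with isotropic Gaussian spread (`site_sigma` = 5 nm), adds
Poisson(`background_rate` = 5) uniform background localizations, drops each
site independently with `misfold_prob` = 0.05 (mimicking misfolded
structures), and applies a random in-plane rotation per ROI. All defaults are
configurable; the seed fully determines the output.

What the generator does *not* emulate: DNA-PAINT photophysics (blinking
kinetics, frame structure, camera noise), localization-precision
heterogeneity, 3D structure, and the long-tailed count distributions of real
origami data. Passing tests on this data therefore demonstrate that the
pipeline recovers class structure from cluster arrangement under realistic
noise — not that it reaches any particular accuracy on real microscopes'
output.

## Problem sizes used by the tests

The scaled-down recovery experiment trains both model variants on 200
synthetic ROIs per class (4 classes, k-means k = 12) at batch size 128 — 50
epochs for ClusterNet-HCF, 30 for ClusterNet-LCF, which converges earlier —
and evaluates on a held-out 20% split; both variants are expected to
recover the classes almost perfectly (HCF ≥ 0.95, LCF ≥ 0.90 balanced
accuracy, HCF ≥ LCF). These sizes are the package's chosen study conditions
for a single-CPU run of a few minutes. The same pipeline applies unchanged to
full-size public DNA-origami benchmark datasets (tens of thousands of ROIs)
under the default 100-epoch schedule; such runs require downloading external
data and substantially more compute, and are intentionally not part of the
test suite.

## Known limitations

* 2D only; the 3D extension (volume features, $\lambda_2 > 0$, 3D rotations)
  is a documented path, not implemented.
* Rotation robustness is learned through augmentation, not architectural; a
  freshly initialized model is not rotation invariant.
* The R-native training loop is practical for graph datasets of thousands of
  ROIs; for much larger corpora a GPU implementation is the right tool.
* DBSCAN uses brute-force neighbourhoods (quadratic in the per-ROI
  localization count), adequate below ~10⁴ localizations per cell.
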