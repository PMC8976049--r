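---
title: "Spatial domain identification with a graph attention auto-encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial domain identification with a graph attention auto-encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial transcriptomics platforms (10x Visium, Slide-seq/V2, Stereo-seq)
measure a gene expression profile at each of thousands of spatially indexed
spots. A *spatial domain* is a contiguous tissue region with a coherent
expression program — a cortical layer, a hippocampal substructure. Clustering
expression alone ignores the spatial arrangement and yields noisy, fragmented
domains, especially on sparse high-resolution platforms. This package learns
low-dimensional spot embeddings that fuse expression similarity with spatial
adjacency, so that clustering the embeddings recovers smooth, contiguous
domains; the same model's decoder output doubles as a denoised expression
matrix, and a cross-section graph extends the construction to aligned 3D
stacks.

## The model

Spots form a *spatial neighbor network* (SNN): an undirected graph with an
edge between spots closer than a radius $r$ (or, for Visium's hexagonal
lattice, each spot's six nearest neighbors, symmetrized by union), plus a
self-loop at every spot. With normalized expressions $x_i$ as initial
embeddings $h_i^{(0)}$, a two-layer encoder produces the final embedding:

$$h_i^{(1)} = \sigma\Big(\sum_{j \in S_i} \mathrm{att}_{ij}\, W_1 h_j^{(0)}\Big),
\qquad h_i^{(2)} = \sigma\big(W_2 h_i^{(1)}\big),$$

where $S_i$ is the neighbor set of spot $i$ (including $i$ itself),
$\sigma$ is the exponential linear unit, and the per-edge weights come from a
graph attention mechanism:

$$e_{ij} = \mathrm{Sigmoid}\big(v_s^\top W_1 h_i^{(0)} + v_r^\top W_1 h_j^{(0)}\big),
\qquad \mathrm{att}_{ij} = \frac{\exp(e_{ij})}{\sum_{j' \in S_i} \exp(e_{ij'})}.$$

The decoder mirrors the encoder with *tied* parameters — its weights are the
exact transposes $W_2^\top, W_1^\top$ and it reuses the encoder's attention
map — so the model has no free decoder parameters:

$$\hat h_i^{(1)} = \sigma\Big(\sum_{j\in S_i}\mathrm{att}_{ij}\,W_2^\top \hat h_j^{(2)}\Big),
\qquad \hat h_i^{(0)} = \sigma\big(W_1^\top \hat h_i^{(1)}\big),$$

with $\hat h^{(2)} = h^{(2)}$. Training minimizes the reconstruction loss
$\sum_i \lVert x_i - \hat h_i^{(0)}\rVert_2^2$ by full-batch Adam; attention
is inside the computation graph, so gradients flow through the softmax and
sigmoid. $h^{(2)}$ (30 dimensions by default) is the embedding used for
clustering; $\hat h^{(0)}$ is the denoised expression.

Two normalization details are deliberate choices. The softmax index is read
as running over $j' \in S_i$, the receiving spot's neighbor set — the only
reading under which each spot's incoming weights form a distribution (they
sum to 1, an invariant the test suite checks at every iteration). And the
loss is implemented as the *squared* 2-norm by default — the standard
auto-encoder objective, smooth at zero — with the plain un-squared norm
available via `stagate_config(loss = "norm")`; both share the
perfect-reconstruction optimum.

### Cell type-aware attention (optional)

For multi-cell-resolution platforms, a coarse Louvain pre-clustering of
expression (resolution 0.2 on 50 PCs, kNN graph with k = 15) defines a
*pruned* SNN that drops edges straddling different pre-clusters. Raw scores
$e_{ij}$ are shared, but normalized separately over the full and pruned
neighbor sets, then blended:
$\mathrm{att} = (1-\alpha)\,\mathrm{att}^{\mathrm{spatial}} + \alpha\,\mathrm{att}^{\mathrm{aware}}$
with $\alpha = 0.5$; pruned-away edges contribute only the spatial term, and
rows still sum to 1. The module is off by default and not recommended at
cellular/subcellular resolution, where pre-clustering tracks technical noise.
The 1000-iteration aware run is a single run with blending active throughout,
not a warm start from a spatial-only phase.

### 3D stacks

For consecutive aligned sections, the 3D SNN is the block-diagonal union of
each section's 2D SNN plus edges between spots of *adjacent* sections whose
in-plane (x, y) distance falls below a user radius; the section offset itself
is ignored (only adjacency of sections matters), and non-adjacent sections
are never linked. Biological structure is continuous across neighboring
sections while technical batch noise is not, so the extra edges let the
attention aggregation smooth over per-section shifts. No default radius is
imposed — it depends on lattice pitch; the 2D radius is a reasonable
starting point.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` / `r` | 6 / — | kNN degree (hexagonal lattice) or radius in chip units; aim for 6–15 mean neighbors |
| `hidden_dims` | (512, 30) | encoder widths; 30 is the embedding dimension |
| `learning_rate` | 1e-4 | Adam step size |
| `weight_decay` | 1e-4 | L2 coefficient added to all parameter gradients |
| `n_iterations` | 500 / 1000 | full-batch iterations (larger with the aware module) |
| `alpha` | 0.5 | aware-attention blend weight |
| `n_top` (HVG) | 3000 | genes kept by dispersion ranking |
| `resolution` (precluster) | 0.2 | deliberately coarse pre-clustering |
| `fdr` | 0.01 | BH threshold for marker calls |

Initialization is Glorot-uniform under a user seed; training is full-batch
and deterministic given the seed, so runs are exactly reproducible.

## Preprocessing decisions

Counts are library-size normalized to a common target (the median library by
default — scale-free, and spots near the median are barely changed), then
`log1p`-transformed. Highly variable genes are ranked by mean-binned
normalized dispersion (variance/mean, z-scored within 20 bins of comparable
mean), computed on the log-normalized matrix; genes with zero variance have
undefined dispersion and are never selected. The binning choice is the
long-standing single-cell default and is isolated in `select_hvg()` so it
can be swapped. For multi-section data HVGs are computed jointly on the
stacked matrix; a per-section selection would couple gene choice to batch
composition, which the 3D graph is meant to absorb downstream.

## Clustering and statistics

With a known domain count the embeddings are clustered by a Gaussian mixture
via `mclust` (equal-covariance `"EEE"` model; deterministic hierarchical
initialization makes it bit-reproducible). Otherwise Louvain communities on
a kNN graph of the embeddings, with an analyst-chosen resolution. Markers
are one-vs-rest Wilcoxon rank-sum tests per gene (normal approximation with
tie correction, cross-checked against `stats::wilcox.test` in the tests),
BH-adjusted within each domain's gene list — per-domain rather than pooled
adjustment, a documented choice that is trivial to switch. Spatial
coherence is measured by Moran's I with the SNN adjacency (self-loops
removed) as binary weights.

## The synthetic tissue generator

`generate_spatial_data()` emulates the benchmark structure this class of
method is evaluated on: a hexagonal (or square, or uniform-random) lattice of
spots; contiguous domains as horizontal layers, concentric rings, or a thin
cord-plus-arrow pair over background (a hippocampus-like geometry);
negative-binomial counts (variance $\mu + \phi\mu^2$) with domain-specific
marker blocks whose means are multiplied by $2^{\mathrm{effect}}$;
log-uniform per-spot library factors; and, for stacks, per-section log-normal
multiplicative gene-mean shifts over identical geometry. The defaults —
1000 spots, 3 layers, 200 genes, 50 markers/domain at 2 log2FC, dispersion
0.5, libraries in [0.5, 2], batch shift sd 0.5 — are the fixed validation
conditions used by the test suite and the acceptance script: overdispersion
and fold change sit in the range typical of UMI platforms and annotated
layer markers, and the batch shift is strong enough that sections analysed
independently yield domain labelings that cannot be matched across
sections, which is precisely the failure mode the inter-section edges
repair.

What the generator does *not* emulate: gene–gene correlation beyond the
domain programs, spatially graded (rather than piecewise-constant)
expression, platform-specific spot geometry artifacts, or histology. Passing
tests therefore demonstrate the machinery — graph construction, optimization,
attention normalization, the denoising and batch-bridging mechanisms — under
controlled conditions, not performance on any real tissue.

## Numerical choices and degenerate inputs

* Gradients are analytic (hand-derived through the tied decoder, the
  softmax, and the attention sigmoid) and are verified against central
  finite differences in the tests; the sparse edge-wise implementation is
  verified against an explicit dense attention-matrix oracle.
* Strict `< r` in the radius rule; ties at exactly `r` are excluded. kNN
  ties at the k-th distance break by spot index, making graphs
  deterministic.
* An isolated spot keeps its self-loop, so its attention softmax is a
  well-defined single-element distribution.
* A spot with zero total count has no defined library scaling and is
  rejected by `lognormalize()` with its id named; dropout simulation at the
  default depths does not produce such spots.
* Divergent training (non-finite loss) aborts with the iteration number
  rather than returning garbage.
* `rowsum()`-based softmax relies on every spot receiving at least one edge,
  which self-loops guarantee by construction.

## Problem sizes

The shipped validation uses 1000-spot sections (300/section for 3D stacks),
200 genes, and the full 512-30 architecture at 500 iterations — small enough
to run comfortably on a laptop CPU in minutes per fit, large enough that
domain recovery, denoising, and batch suppression are non-trivial. The
per-edge kernels are C++ (via Rcpp); everything else is base R linear
algebra.

## Known limitations

* Intra- and inter-section edges are treated identically in the 3D graph; a
  platform with very different in-plane and axial spacing may need a
  different inter-section radius than the 2D one.
* The mixture clustering fixes the component count; model selection over k
  is out of scope.
* Full-batch training holds all intermediates in memory; very large sections
  (≫ 10⁵ spots) would need mini-batching over subgraphs, which this
  implementation does not provide.
* The attention mechanism is single-headed, matching the reference
  architecture.
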