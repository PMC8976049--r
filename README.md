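# stagate

Spatial domain identification, expression denoising, and 3D domain
extraction for spatial transcriptomics, via a graph attention auto-encoder
with tied encoder/decoder weights.

## What it does

Spatial transcriptomics assigns an expression profile to each of thousands
of spatially indexed spots. Clustering expression alone produces fragmented,
noisy domains because it ignores where the spots sit. This package learns a
low-dimensional embedding per spot that fuses both signals: spots form a
*spatial neighbor network* (SNN; radius rule or 6-nearest-neighbor rule for
Visium's hexagonal lattice, self-loops included), and a two-layer graph
attention encoder aggregates each spot's neighborhood with learned per-edge
weights,

```
h_i(1) = ELU( Σ_{j∈S_i} att_ij · W1 x_j ),   h_i(2) = ELU( W2 h_i(1) )
att_ij = softmax_{j∈S_i} Sigmoid( v_sᵀ W1 x_i + v_rᵀ W1 x_j )
```

The decoder mirrors the encoder with *tied* weights (`W2ᵀ`, `W1ᵀ`) and the
same attention map, and the model minimizes the reconstruction error
`Σ_i ‖x_i − x̂_i‖²` by full-batch Adam. The 30-dimensional embedding
`h(2)` is clustered into spatial domains (Gaussian mixture via mclust when
the domain count is known, Louvain otherwise); the reconstruction `x̂` is a
spatially denoised expression matrix. For aligned consecutive sections, a
3D SNN (per-section 2D graphs + edges between in-plane neighbors of
adjacent sections) lets the same machinery suppress section batch effects.

It is intended for analysts of Visium / Slide-seq / Stereo-seq-style data
who want contiguous spatial domains, cleaner spatial expression patterns,
and cross-section consistency, with every stage scriptable from R or the
shell.

## Worked example

Everything below runs on simulated tissue with known ground truth — a
hexagonal lattice with three layered domains, negative-binomial counts,
50 marker genes per domain:

```r
library(stagate)

sim  <- generate_spatial_data(synthetic_spec(n_spots = 400, n_genes = 100,
                                             n_markers_per_domain = 20, seed = 1))
expr <- select_hvg(lognormalize(sim$raw), n_top = 100)
snn  <- build_knn_snn(sim$raw$coords, k = 6)
snn
#> snn (knn): 400 spots, mean 6.34 neighbors/spot

fit <- stagate_train(expr, snn, config = stagate_config(seed = 1, n_iterations = 300))
fit
#> stagate_fit: 400 spots, 30 embedding dims; 300 iterations, final loss 18016.6

domains <- cluster_gmm(fit$embeddings, k = 3, seed = 1)
cluster_metrics(domains, sim$labels)$ari
#> [1] 1
```

The mixture model on the learned embeddings recovers the three planted
layers exactly (adjusted Rand index 1). Marker detection per recovered
domain (one-vs-rest Wilcoxon, BH-adjusted):

```r
markers <- rank_markers(expr, domains, fdr = 0.01)
head(markers[markers$domain == 1, c("gene", "stat", "p_adjusted")], 3)
#>     gene     stat   p_adjusted
#> 1  gene4 13.39285 6.657482e-39
#> 2 gene11 13.06046 2.769465e-37
#> 3 gene18 12.94765 8.074959e-37
```

`gene4`, `gene11`, `gene18` are among the genes the simulator planted as
domain-1 markers (positive `stat` = enriched inside the domain). Denoising:
the decoder reconstruction raises the spatial autocorrelation (Moran's I)
of a marker gene from 0.29 in the noisy input to 0.98:

```r
g <- paste0("gene", sim$marker_genes[[1]][1])
c(raw      = morans_i(expr$values[, g], snn),
  denoised = morans_i(denoised_expression(fit)$values[, g], snn))
#>       raw  denoised
#> 0.2948424 0.9838585
```

`run_pipeline()` chains all stages (filter → normalize → HVG → graph →
train → cluster → markers) and writes embeddings, denoised matrix, labels,
markers, attention edges, loss history, and a provenance JSON. The same
pipeline is available from the shell:

```sh
Rscript inst/cli/stagate.R simulate --n-spots 400 --seed 1 --out sim/
Rscript inst/cli/stagate.R run --input sim/ --n-domains 3 --seed 1 --out results/
```

## Package layout

* `R/preprocess.R` — tissue filter, library-size log-normalization, HVG
  selection by binned dispersion
* `R/graphs.R` — radius / kNN SNNs, Louvain pre-clustering, cell type-aware
  pruning, 3D multi-section graphs
* `R/model.R`, `src/edge_ops.cpp` — the graph attention auto-encoder:
  attention scoring and normalization, tied encode/decode, analytic
  gradients, Adam training loop
* `R/downstream.R` — GMM/Louvain domain calling, Wilcoxon markers with BH
  control, Moran's I, agreement metrics
* `R/synthetic.R` — negative-binomial lattice tissue simulator with ground
  truth
* `R/io.R` — MTX/CSV readers and writers, edge-list TSVs, the end-to-end
  pipeline with provenance
* `vignettes/methods.Rmd` — the model, its assumptions, parameter meanings,
  and the design decisions
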