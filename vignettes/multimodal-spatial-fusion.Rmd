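---
title: "Multimodal spatial fusion: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal spatial fusion: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell spatial transcriptomics (CosMx-style panels, Visium spots)
measures gene expression with preserved tissue coordinates, but the counts
are sparse and noisy: a large fraction of truly expressed genes are observed
as zeros (dropout). The same tissue section usually comes with a
co-registered histology image whose local morphology correlates with the
underlying tissue domain. `stfuse` exploits that second modality: it fuses
per-cell image features with expression over a spatial neighbor graph to
(i) produce a denoised ("enhanced") expression matrix and (ii) yield a
per-cell embedding whose clusters recover annotated spatial domains.

## The model

Cells are nodes of a spatial graph; two cells are neighbors when their
Euclidean pixel distance is at most a radius *r* (closed ball, no
self-loops stored). The working radii on the reference tissues are 80 px
(lung), 300 px (breast) and 20 px (colorectal), chosen so that average
neighbor counts are comparable across datasets; `neighbor_stats()` reports
the quantities used for that tuning.

Three graph-transformer autoencoders share this graph:

* the **image autoencoder** encodes per-cell image features
  $z_{M,i}$,
* the **transcriptome autoencoder** encodes the preprocessed expression
  $z_{g,i}$,
* the **hybrid autoencoder** encodes the concatenation
  $[z_{M,i}, z_{g,i}]$ into the terminal embedding $z_{h,i}$.

Every encoder/decoder layer is a *neighbor-attention* layer: the output row
for cell $i$ is a softmax-weighted sum of value-projected inputs over
$\{i\} \cup \mathcal{N}(i)$, with scaled dot-product scores between the
query of $i$ and the keys of its neighborhood, followed by an ELU
(the final decoder layer is linear). Encoders are two layers
(input → hidden → latent; defaults 64 and 32), decoders mirror them with
independent weights. With no neighbors the softmax is a singleton and the
layer degenerates to a per-cell dense layer, which is how the tests pin its
semantics.

Training is self-supervised. With $X$ the normalized log expression, the
loss is

$$L = \lambda_1\,\mathrm{MSE}(\hat{X}_{img}, X) +
      \lambda_2\,\mathrm{MSE}(\hat{X}_{gene}, X) +
      \mathrm{MSE}(\hat{X}_{hyb}, X), \qquad \lambda_1, \lambda_2 \ge 0,$$

with both weights 0.1 by default. All three branches reconstruct gene
space; the image branch therefore learns to predict expression from
morphology. (The alternative, reconstructing its own input features, is
available via `recon_img_target = "image"`.) Optimization is full-graph
Adam, learning rate 0.001, weight decay 1e-4, gradients clipped to a global
norm of 5, 1,000 epochs by default. The enhanced expression is the hybrid
reconstruction clipped below at zero, since normalized log expression is
non-negative.

Two further training choices matter and are this package's own:

* **Gene encoder input scaling.** The attention scores are dot products; on
  raw log-normalized values (entries up to ~7) they start far outside the
  softmax's linear regime, so attention collapses to near-one-hot weights at
  initialization and the spatial smoothing the layer should provide is lost.
  The gene *encoder input* is therefore per-gene standardized
  (zero mean, unit variance), while the loss target remains the normalized
  log layer itself. Image features are standardized for the same reason
  (`standardize_features()`, a tested step of its own).
* **Denoising-style input corruption.** At desk scale (hundreds to a few
  thousand cells) full-batch reconstruction training begins to memorize the
  observed zero pattern after roughly 150 epochs, which degrades both the
  embedding and the denoised output. Each epoch therefore corrupts the
  encoder inputs by zeroing a random fraction (default 0.5 — on the order of
  the dropout rate the denoiser is meant to remove — with inverted-dropout
  rescaling, drawn from the seeded stream); the target is never corrupted.
  This is the classical denoising-autoencoder device and is controlled by
  `train_config(input_corruption =)`; set it to 0 for clean-input training.

## Preprocessing

Fixed order: gene-name deduplication (first occurrence unchanged, k-th
duplicate suffixed `-(k-1)`, suffix collisions bumped), per-cell total
normalization, `log1p`. The per-cell target total defaults to 10,000 — the
field-standard scale; what matters for the model is only that the scale is
consistent across cells, and the value is configurable. The composed transform
preserves within-row rank order. An optional top-k-variance gene filter is
off by default. Patches are cell-centered `3 x size x size` crops (default
240 px side) in a half-open pixel window; out-of-image pixels are zero
(black) padding — deterministic and detectable in tests; non-integer
coordinates are rounded half-away-from-zero.

## Image features

The built-in extractor is deliberately simple and fully deterministic:
per-channel intensity histograms over a 3×3 spatial grid, per-channel
mean/sd, and a gradient-magnitude histogram (454 dimensions at the
defaults). It captures the coarse color/texture contrasts that distinguish
tissue domains, runs offline, and needs no weights. Pretrained pathology
backbones (CTransPath/UNI-class models) plug in behind the same
`feature_extractor` protocol, either as an `extract` function or as
precomputed per-cell embeddings loaded with `load_precomputed_features()`
(rows re-aligned by `cell_id`); their internals are out of scope here and
tests never require them.

## Downstream analyses

* **Clustering.** Spatial-domain benchmarks in this literature presuppose a
  known k, so the default clusterer is a Gaussian mixture (common
  covariance, `mclust`, `modelNames = "EEE"`) with fixed k on $z_h$;
  k-means is available. Labels are integers in `[0, k)`.
* **ARI.** Chance-corrected pair counting from the contingency table with
  binomial coefficients; 1 for identical partitions, ~0 at chance, negative
  below chance. The implementation is tested against an independent
  $O(n^2)$ pair-counting oracle and a library implementation.
* **Marker genes.** One-vs-rest two-sided Wilcoxon rank-sum per gene per
  cluster, Benjamini–Hochberg within cluster, DEG = adjusted p < 0.05 and
  |log2 fold change| ≥ 0.25 (both configurable). The log fold change is
  computed on the expm1 scale of the supplied layer.
* **Raw-vs-enhanced tests.** A *paired* two-sided t-test on
  `enhanced - raw` over the same cells (optionally within a region mask).
  Zero-variance nonzero-mean differences report the smallest representable
  positive p with a direction rather than failing. A two-sample
  region-contrast design would also be defensible; the paired default is the
  documented choice.
* **2-D projection.** `project_2d()` is a seeded, sign-fixed principal
  component projection. It is deterministic by construction and preserves
  the separation of well-separated clusters, which is all the package's
  visual checks rely on; a nonlinear neighbor-embedding is deliberately not
  reimplemented here.

## The synthetic benchmark

`generate_benchmark()` draws: uniform cell coordinates on a square tissue
(for the stripe layout, cells are allocated evenly across bands so nucleus
density cannot encode stripe identity — this enforces the conditional
independence of image and expression noise given the labels); domain labels
by layout (equal vertical stripes by default; Gaussian-blob and Voronoi
layouts available); negative-binomial counts with mean
`base_mean * 2^(marker_lfc)` for a gene in its marker domain
(variance $\mu + \alpha\mu^2$; $\alpha = 0$ gives Poisson); independent
Bernoulli dropout recorded in a mask; and a histology image whose per-domain
base color and procedural texture are scaled by `texture_contrast`, with
domain-independent speckle and dark nuclei at cell positions. Defaults:
800 cells, 200 genes, 4 domains, 10 markers/domain at log2 fold change 2,
base mean 0.5 counts (a realistic targeted-panel occupancy), overdispersion
0.5, dropout 0.6, 480-px image, contrast 0.8. At contrast 0 the image
carries no domain signal at all, which is the ablation used to attribute
fusion gains to the image modality. Image noise and expression noise are
conditionally independent given the domain labels.

What the generator does *not* emulate: within-domain spatial autocorrelation
of expression beyond domain membership, realistic H&E stain appearance,
library-size gradients, and segmentation errors. Passing the built-in
benchmarks therefore demonstrates correct mechanics and the fusion premise,
not performance on real tissue.

On this benchmark the package's own measurements (reproduced by
`scripts/acceptance.R`) show the intended ordering: image-feature principal
components separate domains almost perfectly, expression PCs are weak under
60% dropout, and the hybrid embedding clusters near the image ceiling while
strictly beating the expression-only baseline; the enhanced matrix
correlates with the noiseless truth far better than the raw observations do.

## Numerical choices and degenerate inputs

* Radius graphs use grid-bucket spatial hashing (closed-ball comparison,
  `<=`); duplicate coordinates at distance 0 are neighbors for any radius.
* Attention softmax is max-shifted per neighborhood; per-node aggregations
  are cumulative-sum segment reductions over the edge list sorted by node.
* Weight init is Glorot-uniform from the seeded global stream
  (`set_global_seed()` pins Mersenne-Twister); fixed seed gives bit-stable
  loss histories on one platform.
* Gradient clipping records the *post-clip* global norm, recomputed from
  the scaled gradients.
* All-zero expression rows stay zero under normalization; empty
  neighborhoods attend to self only; constant feature columns standardize
  to zero; GMM failures fall back to seeded k-means.

## Desk-scale profile and a known loss-floor limitation

Tests and the acceptance script run the full pipeline at 800 cells,
200 genes, 48-px patches, radius 30 px (mean degree ≈ 10, matching the
comparable-neighbor-count rule) and 200 training epochs — sizes chosen so a
single CPU finishes in minutes while every qualitative property of the
full-scale protocol is exercised.

One quantitative caveat follows from the noise model, not from the
optimizer: under 60% dropout the normalized-log target is approximately
`v * Bernoulli(q)` per entry with occupancy `q ≈ 0.13`, so even the
Bayes-optimal per-entry predictor retains about `1 - q ≈ 87%` of the
zero-predictor's MSE. The *training* loss therefore cannot fall below
roughly 0.8× its initial value at this sparsity without memorizing noise —
which the input corruption deliberately prevents. The loss history is still
required (and tested) to decrease monotonically in trend; the useful signal
of fit quality on this benchmark is the denoising correlation and the
domain-recovery ARI, not the raw loss ratio.

## Known limitations

* The hybrid embedding inherits whatever the image modality encodes; on
  tissues where morphology is uninformative the fusion gain disappears (the
  contrast-0 ablation quantifies this), and the spatial graph alone still
  confers an advantage over non-spatial clustering through neighborhood
  smoothing.
* Full-graph training holds all intermediate activations; ~10^5-cell
  datasets fit memory but per-epoch cost grows linearly in edges.
  Neighborhood-sampled minibatching is an extension point, off by default.
* FOV boundaries are ignored by default when building the graph (cells
  within the radius are linked regardless of FOV).
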