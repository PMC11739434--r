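# stfuse

Multimodal fusion of histology and spatial transcriptomics with
graph-attention autoencoders.

## What it does, and for whom

Single-cell spatial transcriptomics (CosMx-style panels, Visium) gives
per-cell gene expression with tissue coordinates, but the counts are sparse:
many truly expressed genes are observed as zeros (dropout), and spatial
domains are hard to delineate from expression alone. The same section
usually comes with a co-registered histology image whose local morphology
tracks tissue domains. `stfuse` is for analysts who want to use that second
modality: it fuses per-cell image features with expression over a spatial
neighbor graph to produce

* a denoised (**enhanced**) expression matrix, and
* a per-cell **hybrid embedding** whose clusters recover spatial domains,

plus the downstream tooling to evaluate both (ARI against annotations,
one-vs-rest marker genes, paired raw-vs-enhanced tests) and a fully seeded
synthetic-tissue simulator so the whole pipeline is testable offline.

## The model

Cells are nodes of a graph with an edge whenever two cells are within a
Euclidean pixel radius *r* (presets: 80 lung / 300 breast / 20 colorectal,
chosen for comparable mean neighbor counts). Three graph-transformer
autoencoders share the graph: an image autoencoder (features
*z<sub>M</sub>*), a transcriptome autoencoder (*z<sub>g</sub>*), and a
hybrid autoencoder that encodes their concatenation into the terminal
embedding *z<sub>h</sub>*. Every layer is neighbor attention — a softmax
over scaled dot-product scores on {cell} ∪ neighbors — and training
minimizes the weighted self-supervised reconstruction loss

L = λ₁·MSE(X̂_img, X) + λ₂·MSE(X̂_gene, X) + MSE(X̂_hyb, X),  λ₁ = λ₂ = 0.1,

with X the normalized log expression, by full-graph Adam (lr 0.001, weight
decay 1e-4, gradient norm clipped at 5, 1,000 epochs by default). The
enhanced matrix is the hybrid reconstruction clipped at zero. Image
features come from a deterministic built-in texture extractor, or from any
pretrained pathology backbone through the `feature_extractor` /
`load_precomputed_features()` adapter. See
`vignettes/multimodal-spatial-fusion.Rmd` for assumptions, parameter
meanings and design choices.

## Worked example

```r
library(stfuse)

# a synthetic tissue: 800 cells, 200 genes, 4 striped domains,
# 60% dropout, histology texture correlated with domain identity
bench <- generate_benchmark(synthetic_config(seed = 1))
ds    <- preprocess_dataset(bench$dataset)        # dedup, normalize, log1p
graph <- build_radius_graph(ds$coords, radius = 30)

fit <- stfuse(ds, image = bench$image, graph = graph,
              patch_size = 48, epochs = 150, seed = 1)
print(fit)
#> Multimodal spatial fusion fit (hybrid graph transformer)
#>   800 cells x 200 genes, image features: builtin-texture(bins=16,grid=3) (454 dims)
#>   graph: radius 30 px, mean degree 9.28
#>   150 epochs: total loss 5.9073 -> 4.882

domains <- cluster_embeddings(predict(fit, "hybrid"), k = 4, seed = 1)
adjusted_rand_index(domains, bench$truth$domain_labels)
#> [1] 0.8517262

# denoising: the enhanced matrix tracks the noiseless truth far better
truth <- log1p_transform(normalize_total(bench$truth$clean_expression))
cor(as.vector(predict(fit, "enhanced")), as.vector(truth))   # 0.693
cor(as.vector(get_layer(ds, "norm")),   as.vector(truth))    # 0.110
```

The ARI of ~0.85 against the planted domains (chance ≈ 0) and the six-fold
jump in truth correlation are the two headline behaviors; an
expression-only baseline (PCA of the normalized layer, same clusterer)
reaches only ~0.16 ARI on this benchmark. `evaluate_benchmark()` wraps this
whole comparison in one call.

A staged command-line interface with the same functionality
(`simulate`, `preprocess`, `graph`, `features`, `train`, `enhance`,
`cluster`, `evaluate`, `deg`) is installed at
`system.file("cli", "stfuse", package = "stfuse")`.

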