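#' Run the full pipeline on a synthetic benchmark and score it
#'
#' Generates a benchmark, preprocesses it, builds the spatial graph, extracts
#' built-in texture features from the rendered histology, fits the fusion
#' model, and scores (i) spatial-domain recovery — ARI of the clustered
#' hybrid embedding against the true domains, next to an expression-only
#' baseline (leading principal components of the normalized layer, same
#' clusterer, same k) — and (ii) denoising — Pearson correlation of the
#' enhanced matrix with the noiseless truth (both compared on the normalized
#' log scale), next to the raw observations.
#'
#' The default problem sizes are the package's desk-scale profile: 150
#' training epochs, 48-px patches, a 30-px neighbor radius (mean degree
#' about 10 on the default 800-cell tissue).
#'
#' @param config a [synthetic_config()]; its seed drives everything.
#' @param epochs training epochs.
#' @param radius neighbor radius in pixels.
#' @param patch_size patch side in pixels.
#' @param n_pcs principal components for the expression-only baseline.
#' @param cluster_method passed to [cluster_embeddings()].
#' @return list with `ari_hybrid`, `ari_baseline`, `cor_enhanced`,
#'   `cor_raw`, the fitted `stfuse` object (`fit`) and the benchmark
#'   `truth`.
#' @export
evaluate_benchmark <- function(config = synthetic_config(), epochs = 150L,
                               radius = 30, patch_size = 48L, n_pcs = 20L,
                               cluster_method = "gmm") {
  bench <- generate_benchmark(config)
  ds <- preprocess_dataset(bench$dataset)
  graph <- build_radius_graph(ds$coords, radius)
  fit <- stfuse(ds, image = bench$image, graph = graph,
                patch_size = patch_size, epochs = epochs,
                seed = config$seed)
  k <- config$k_domains
  truth_labels <- bench$truth$domain_labels
  lab_h <- cluster_embeddings(predict(fit, "hybrid"), k, seed = config$seed,
                              method = cluster_method)
  Xn <- get_layer(fit$dataset, "norm")
  pcs <- stats::prcomp(Xn, rank. = min(n_pcs, ncol(Xn) - 1L))$x
  lab_b <- cluster_embeddings(pcs, k, seed = config$seed,
                              method = cluster_method)
  truth_norm <- log1p_transform(normalize_total(bench$truth$clean_expression))
  list(ari_hybrid = adjusted_rand_index(lab_h, truth_labels),
       ari_baseline = adjusted_rand_index(lab_b, truth_labels),
       cor_enhanced = stats::cor(as.vector(predict(fit, "enhanced")),
                                 as.vector(truth_norm)),
       cor_raw = stats::cor(as.vector(Xn), as.vector(truth_norm)),
       fit = fit, truth = bench$truth)
}
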