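#' Fit the multimodal spatial fusion model
#'
#' The central fitting function: takes a spatial dataset and either a
#' co-registered histology image or precomputed per-cell image features,
#' preprocesses the expression (dedup, per-cell normalization, log1p), builds
#' the Euclidean-radius neighbor graph, extracts and standardizes image
#' features, and trains the three-autoencoder hybrid graph transformer with
#' the weighted self-supervised reconstruction loss. Returns a fitted object
#' whose hybrid embedding is used for spatial-domain clustering and whose
#' hybrid reconstruction is the denoised ("enhanced") expression.
#'
#' @param dataset a `spatial_dataset`.
#' @param image optional `histology_image` in the same pixel frame.
#' @param features optional precomputed `feature_matrix` (or plain matrix);
#'   exactly one of `image` / `features` must be supplied.
#' @param radius neighbor radius in pixels (see [tissue_radius()] for the
#'   per-tissue presets 80/300/20).
#' @param graph optional prebuilt `spatial_graph` (overrides `radius`).
#' @param patch_size cell-centered patch side in pixels when extracting from
#'   `image` (default 240).
#' @param extractor a `feature_extractor` (default: built-in texture).
#' @param target_sum per-cell normalization total.
#' @param hidden_dim,latent_dim,n_heads,lambda1,lambda2,recon_img_target
#'   model hyperparameters, see [model_config()].
#' @param epochs,lr,grad_clip_norm,weight_decay,input_corruption,seed
#'   training hyperparameters, see [train_config()].
#' @param log_every progress frequency (0 = silent).
#' @return An object of class `stfuse`.
#' @seealso [predict.stfuse()], [enhance_expression()], [cluster_embeddings()]
#' @export
stfuse <- function(dataset, image = NULL, features = NULL, radius = NULL,
                   graph = NULL, patch_size = 240L,
                   extractor = texture_extractor(), target_sum = 1e4,
                   hidden_dim = 64L, latent_dim = 32L, n_heads = 1L,
                   lambda1 = 0.1, lambda2 = 0.1,
                   recon_img_target = "expression",
                   epochs = 1000L, lr = 0.001, grad_clip_norm = 5,
                   weight_decay = 1e-4, input_corruption = 0.5, seed = 1L,
                   log_every = 0L) {
  cl <- match.call()
  if (!inherits(dataset, "spatial_dataset")) {
    stopf("dataset must be a spatial_dataset")
  }
  if (is.null(image) && is.null(features)) {
    stopf("supply either a histology image or precomputed features")
  }
  if (!"norm" %in% names(dataset$layers)) {
    dataset <- preprocess_dataset(dataset, target_sum = target_sum)
  }
  if (is.null(graph)) {
    if (is.null(radius)) stopf("supply a radius or a prebuilt graph")
    graph <- build_radius_graph(dataset$coords, radius)
  }
  if (is.null(features)) {
    patches <- crop_patches(image, dataset, size = patch_size)
    features <- extract_features(patches, extractor)
  } else if (!inherits(features, "feature_matrix")) {
    features <- structure(list(values = as.matrix(features),
                               extractor_name = "user-supplied"),
                          class = "feature_matrix")
  }
  if (nrow(features$values) != nrow(dataset$expression)) {
    stopf("feature matrix has %d rows for %d cells",
          nrow(features$values), nrow(dataset$expression))
  }
  features <- standardize_features(features)
  X <- get_layer(dataset, "norm")
  mcfg <- model_config(gene_dim = ncol(X), img_dim = ncol(features$values),
                       hidden_dim = hidden_dim, latent_dim = latent_dim,
                       n_heads = n_heads, lambda1 = lambda1,
                       lambda2 = lambda2,
                       recon_img_target = recon_img_target)
  tcfg <- train_config(lr = lr, epochs = epochs,
                       grad_clip_norm = grad_clip_norm,
                       weight_decay = weight_decay,
                       input_corruption = input_corruption, seed = seed,
                       log_every = log_every)
  set_global_seed(tcfg$seed)
  params <- init_model(mcfg)
  fit <- run_training(params, X, features$values, graph, mcfg, tcfg)
  bundle <- model_forward(gene_encoder_input(X), features$values, graph,
                          fit$params, mcfg)
  enhanced <- pmax(bundle$recon_hyb, 0)
  dataset <- set_layer(dataset, "enhanced", enhanced)
  structure(list(params = fit$params, history = fit$history,
                 model_config = mcfg, config = tcfg, graph = graph,
                 features = features, dataset = dataset,
                 bundle = bundle[c("z_img", "z_gene", "z_hyb", "recon_img",
                                   "recon_gene", "recon_hyb")],
                 extractor_name = features$extractor_name, call = cl),
            class = "stfuse")
}

#' @export
print.stfuse <- function(x, ...) {
  cat("Multimodal spatial fusion fit (hybrid graph transformer)\n")
  cat(sprintf("  %d cells x %d genes, image features: %s (%d dims)\n",
              nrow(x$dataset$expression), ncol(x$dataset$expression),
              x$extractor_name, x$model_config$img_dim))
  cat(sprintf("  graph: radius %g px, mean degree %.2f\n",
              x$graph$radius, neighbor_stats(x$graph)$mean_degree))
  h <- x$history
  cat(sprintf("  %d epochs: total loss %.5g -> %.5g\n",
              nrow(h), h$total[1L], h$total[nrow(h)]))
  invisible(x)
}

#' @export
summary.stfuse <- function(object, ...) {
  h <- object$history
  s <- list(n_cells = nrow(object$dataset$expression),
            n_genes = ncol(object$dataset$expression),
            img_dim = object$model_config$img_dim,
            latent_dim = object$model_config$latent_dim,
            epochs = nrow(h),
            initial_loss = h$total[1L], final_loss = h$total[nrow(h)],
            loss_ratio = h$total[nrow(h)] / h$total[1L],
            max_grad_norm = max(h$grad_norm),
            mean_degree = neighbor_stats(object$graph)$mean_degree,
            lambda1 = object$model_config$lambda1,
            lambda2 = object$model_config$lambda2,
            seed = object$config$seed)
  class(s) <- "summary.stfuse"
  s
}

#' @export
print.summary.stfuse <- function(x, ...) {
  cat("Hybrid graph transformer fit\n")
  cat(sprintf("  data: %d cells x %d genes; image features %d dims; latent %d\n",
              x$n_cells, x$n_genes, x$img_dim, x$latent_dim))
  cat(sprintf("  graph mean degree: %.2f\n", x$mean_degree))
  cat(sprintf("  loss (lambda1 = %g, lambda2 = %g): %.5g -> %.5g over %d epochs (ratio %.3f)\n",
              x$lambda1, x$lambda2, x$initial_loss, x$final_loss, x$epochs,
              x$loss_ratio))
  cat(sprintf("  max post-clip gradient norm: %.4g; seed %d\n",
              x$max_grad_norm, x$seed))
  invisible(x)
}

#' Predict from a fitted fusion model
#'
#' @param object a `stfuse` fit.
#' @param type `"enhanced"` (denoised expression, clipped at 0), `"hybrid"`,
#'   `"gene"` or `"image"` (the per-cell embeddings), or `"reconstruction"`
#'   (the unclipped hybrid reconstruction).
#' @param ... unused.
#' @return A cells x genes or cells x latent matrix.
#' @export
predict.stfuse <- function(object, type = c("enhanced", "hybrid", "gene",
                                            "image", "reconstruction"), ...) {
  type <- match.arg(type)
  b <- object$bundle
  switch(type,
         enhanced = pmax(b$recon_hyb, 0),
         hybrid = b$z_hyb,
         gene = b$z_gene,
         image = b$z_img,
         reconstruction = b$recon_hyb)
}

#' @export
fitted.stfuse <- function(object, ...) pmax(object$bundle$recon_hyb, 0)

#' @export
residuals.stfuse <- function(object, ...) {
  get_layer(object$dataset, "norm") - object$bundle$recon_hyb
}

#' @export
coef.stfuse <- function(object, ...) object$params

#' Plot the training loss history
#'
#' @param x a `stfuse` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stfuse <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "total loss", ...)
  graphics::lines(h$epoch, h$L_hyb, lty = 2L)
  graphics::legend("topright", legend = c("total", "hybrid branch"),
                   lty = c(1L, 2L), bty = "n")
  invisible(x)
}
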