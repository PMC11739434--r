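#' Fusion model configuration
#'
#' Dimensions and loss weights of the hybrid graph-transformer: three
#' neighbor-attention autoencoders (image, transcriptome, hybrid) whose total
#' loss is `lambda1 * L_img + lambda2 * L_gene + L_hyb`, each branch an MSE
#' against the normalized log expression.
#'
#' @param gene_dim number of genes (input/output width of the gene branch).
#' @param img_dim image feature dimension.
#' @param hidden_dim attention layer width (default 64).
#' @param latent_dim embedding width (default 32).
#' @param n_heads attention heads (default 1); must divide `hidden_dim` and
#'   `latent_dim`.
#' @param lambda1 weight of the image-branch reconstruction loss (default 0.1).
#' @param lambda2 weight of the gene-branch reconstruction loss (default 0.1).
#' @param recon_img_target `"expression"` (default: the image branch learns to
#'   predict expression from morphology) or `"image"` (it reconstructs its own
#'   input features).
#' @return An object of class `model_config`.
#' @export
model_config <- function(gene_dim, img_dim, hidden_dim = 64L,
                         latent_dim = 32L, n_heads = 1L,
                         lambda1 = 0.1, lambda2 = 0.1,
                         recon_img_target = c("expression", "image")) {
  recon_img_target <- match.arg(recon_img_target)
  cfg <- list(gene_dim = as.integer(gene_dim), img_dim = as.integer(img_dim),
              hidden_dim = as.integer(hidden_dim),
              latent_dim = as.integer(latent_dim), n_heads = as.integer(n_heads),
              lambda1 = lambda1, lambda2 = lambda2,
              recon_img_target = recon_img_target)
  if (any(unlist(cfg[1:5]) < 1L)) stopf("all model dimensions must be >= 1")
  if (cfg$lambda1 < 0 || cfg$lambda2 < 0) stopf("lambda1, lambda2 must be >= 0")
  if (cfg$hidden_dim %% cfg$n_heads != 0L ||
      cfg$latent_dim %% cfg$n_heads != 0L) {
    stopf("n_heads must divide hidden_dim and latent_dim")
  }
  structure(cfg, class = "model_config")
}

elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0))

# Glorot-uniform init of one attention layer: per-head query/key/value
# projections plus an output bias
init_attn_layer <- function(d_in, d_out, n_heads) {
  dh <- d_out %/% n_heads
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  heads <- lapply(seq_len(n_heads), function(h) {
    list(Wq = glorot(d_in, dh), Wk = glorot(d_in, dh), Wv = glorot(d_in, dh))
  })
  list(heads = heads, b = numeric(d_out))
}

init_autoencoder <- function(d_in, hidden, latent, d_out, n_heads) {
  list(enc1 = init_attn_layer(d_in, hidden, n_heads),
       enc2 = init_attn_layer(hidden, latent, n_heads),
       dec1 = init_attn_layer(latent, hidden, n_heads),
       dec2 = init_attn_layer(hidden, d_out, n_heads))
}

#' Initialize fusion model weights
#'
#' Glorot-style uniform initialization from the current RNG state; call
#' [set_global_seed()] first for reproducibility.
#'
#' @param config a `model_config`.
#' @return Nested list of weight matrices (image, gene, hybrid autoencoders).
#' @export
init_model <- function(config) {
  img_out <- if (config$recon_img_target == "image") config$img_dim else
    config$gene_dim
  list(
    img = init_autoencoder(config$img_dim, config$hidden_dim,
                           config$latent_dim, img_out, config$n_heads),
    gene = init_autoencoder(config$gene_dim, config$hidden_dim,
                            config$latent_dim, config$gene_dim,
                            config$n_heads),
    hyb = init_autoencoder(2L * config$latent_dim, config$hidden_dim,
                           config$latent_dim, config$gene_dim,
                           config$n_heads))
}

agg_src <- function(ai, x) segment_sum(x, ai$ends_src)
agg_dst <- function(ai, x) {
  segment_sum(if (is.matrix(x)) x[ai$ord_dst, , drop = FALSE]
              else x[ai$ord_dst], ai$ends_dst)
}
agg_src_vec <- agg_src

# one neighbor-attention layer: each cell attends over itself plus its
# spatial neighbors with softmaxed scaled dot-product weights. Internally
# everything is transposed (features x cells) so the compiled edge kernels
# (src/attention_ops.cpp) touch contiguous columns; the public orientation
# stays cells x features.
attn_forward <- function(H, ai, layer, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  n <- nrow(H)
  n_heads <- length(layer$heads)
  dh <- ncol(layer$heads[[1L]]$Wv)
  Ht <- t(H)
  Mts <- vector("list", n_heads)
  hc <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    p <- layer$heads[[h]]
    Qt <- crossprod(p$Wq, Ht)
    Kt <- crossprod(p$Wk, Ht)
    Vt <- crossprod(p$Wv, Ht)
    e <- edge_dot(Qt, Kt, ai$src, ai$dst) / sqrt(dh)
    a <- edge_softmax(e, ai$ends_src)
    Mts[[h]] <- edge_scatter(Vt, ai$dst, a, ai$src, n)
    hc[[h]] <- list(Qt = Qt, Kt = Kt, Vt = Vt, a = a)
  }
  Mt <- do.call(rbind, Mts) + layer$b   # b recycles down rows = per feature
  out <- t(if (activation == "elu") elu(Mt) else Mt)
  list(out = out, cache = list(Ht = Ht, Mt = Mt, heads = hc,
                               activation = activation, dh = dh))
}

# backward pass of one attention layer; returns weight gradients and the
# gradient w.r.t. the layer input
attn_backward <- function(dOut, cache, layer, ai) {
  dMt <- t(dOut)
  if (cache$activation == "elu") dMt <- dMt * elu_grad(cache$Mt)
  db <- .rowSums(dMt, nrow(dMt), ncol(dMt))
  Ht <- cache$Ht
  dh <- cache$dh
  n <- ncol(Ht)
  n_heads <- length(layer$heads)
  dHt <- matrix(0, nrow(Ht), n)
  gheads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    p <- layer$heads[[h]]
    ch <- cache$heads[[h]]
    dMth <- dMt[((h - 1L) * dh + 1L):(h * dh), , drop = FALSE]
    dVt <- edge_scatter(dMth, ai$src, ch$a, ai$dst, n)
    dalpha <- edge_dot(dMth, ch$Vt, ai$src, ai$dst)
    s <- vec_segment_sum(ch$a * dalpha, ai$ends_src)
    de <- ch$a * (dalpha - s[ai$src]) / sqrt(dh)
    dQt <- edge_scatter(ch$Kt, ai$dst, de, ai$src, n)
    dKt <- edge_scatter(ch$Qt, ai$src, de, ai$dst, n)
    gheads[[h]] <- list(Wq = tcrossprod(Ht, dQt), Wk = tcrossprod(Ht, dKt),
                        Wv = tcrossprod(Ht, dVt))
    dHt <- dHt + p$Wq %*% dQt + p$Wk %*% dKt + p$Wv %*% dVt
  }
  list(grads = list(heads = gheads, b = db), dH = t(dHt))
}

# autoencoder forward: enc1 -> enc2 (= embedding z) -> dec1 -> dec2 (linear)
ae_forward <- function(X, ai, params) {
  f1 <- attn_forward(X, ai, params$enc1, "elu")
  f2 <- attn_forward(f1$out, ai, params$enc2, "elu")
  f3 <- attn_forward(f2$out, ai, params$dec1, "elu")
  f4 <- attn_forward(f3$out, ai, params$dec2, "identity")
  list(z = f2$out, recon = f4$out, caches = list(f1$cache, f2$cache,
                                                 f3$cache, f4$cache))
}

# autoencoder backward: dRecon flows through the decoder; dZ_extra is the
# gradient arriving at the embedding from elsewhere (the hybrid branch)
ae_backward <- function(dRecon, dZ_extra, fwd, params, ai) {
  b4 <- attn_backward(dRecon, fwd$caches[[4L]], params$dec2, ai)
  b3 <- attn_backward(b4$dH, fwd$caches[[3L]], params$dec1, ai)
  dZ <- b3$dH
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  b2 <- attn_backward(dZ, fwd$caches[[2L]], params$enc2, ai)
  b1 <- attn_backward(b2$dH, fwd$caches[[1L]], params$enc1, ai)
  list(grads = list(enc1 = b1$grads, enc2 = b2$grads,
                    dec1 = b3$grads, dec2 = b4$grads),
       dInput = b1$dH)
}

#' Forward pass of the hybrid graph transformer
#'
#' The image autoencoder encodes the standardized image features, the
#' transcriptome autoencoder the normalized log expression; their embeddings
#' are concatenated and fed to the hybrid autoencoder, whose attention layers
#' also run over the spatial graph. Each encoder/decoder layer is a
#' neighbor-attention layer.
#'
#' @param gene_X cells x gene_dim normalized log expression.
#' @param img_F cells x img_dim standardized image features.
#' @param graph a `spatial_graph` over the same cells.
#' @param params weights from [init_model()].
#' @param config the `model_config`.
#' @param ai precomputed attention index (internal; built from `graph` if
#'   missing).
#' @return An `embedding_bundle`: `z_img`, `z_gene`, `z_hyb` (cells x
#'   latent_dim), `recon_img`, `recon_gene`, `recon_hyb`, plus forward caches
#'   for backprop.
#' @export
model_forward <- function(gene_X, img_F, graph, params, config, ai = NULL) {
  gene_X <- as.matrix(gene_X)
  img_F <- as.matrix(img_F)
  if (ncol(gene_X) != config$gene_dim || ncol(img_F) != config$img_dim) {
    stopf("input widths (%d genes, %d image dims) do not match config (%d, %d)",
          ncol(gene_X), ncol(img_F), config$gene_dim, config$img_dim)
  }
  if (nrow(gene_X) != graph$n_cells || nrow(img_F) != graph$n_cells) {
    stopf("graph covers %d cells but inputs have %d / %d rows",
          graph$n_cells, nrow(gene_X), nrow(img_F))
  }
  if (is.null(ai)) ai <- attention_index(graph)
  fi <- ae_forward(img_F, ai, params$img)
  fg <- ae_forward(gene_X, ai, params$gene)
  fh <- ae_forward(cbind(fi$z, fg$z), ai, params$hyb)
  for (nm in c("z", "recon")) {
    for (br in list(img = fi, gene = fg, hyb = fh)) {
      if (!all(is.finite(br[[nm]]))) {
        stopf("non-finite values in the model %s output", nm)
      }
    }
  }
  structure(list(z_img = fi$z, z_gene = fg$z, z_hyb = fh$z,
                 recon_img = fi$recon, recon_gene = fg$recon,
                 recon_hyb = fh$recon,
                 .fwd = list(img = fi, gene = fg, hyb = fh, ai = ai)),
            class = "embedding_bundle")
}

#' Weighted self-supervised reconstruction loss
#'
#' Per branch, the mean squared error over all matrix entries against the
#' normalized log expression (or, for the image branch when configured, its
#' own input features); the total is
#' `lambda1 * L_img + lambda2 * L_gene + L_hyb`.
#'
#' @param bundle an `embedding_bundle` from [model_forward()].
#' @param target cells x gene_dim normalized log expression.
#' @param config the `model_config`.
#' @param img_target target of the image branch when
#'   `recon_img_target = "image"` (the standardized features).
#' @return A `loss_breakdown`: `L_img`, `L_gene`, `L_hyb`, `total`.
#' @export
compute_loss <- function(bundle, target, config, img_target = NULL) {
  target <- as.matrix(target)
  it <- if (config$recon_img_target == "image") {
    if (is.null(img_target)) stopf("img_target required when the image branch reconstructs its input")
    as.matrix(img_target)
  } else target
  for (pair in list(list(bundle$recon_img, it, "image"),
                    list(bundle$recon_gene, target, "gene"),
                    list(bundle$recon_hyb, target, "hybrid"))) {
    if (!identical(dim(pair[[1L]]), dim(pair[[2L]]))) {
      stopf("%s reconstruction shape (%d, %d) does not match its target (%d, %d)",
            pair[[3L]], nrow(pair[[1L]]), ncol(pair[[1L]]),
            nrow(pair[[2L]]), ncol(pair[[2L]]))
    }
  }
  L_img <- mean((bundle$recon_img - it)^2)
  L_gene <- mean((bundle$recon_gene - target)^2)
  L_hyb <- mean((bundle$recon_hyb - target)^2)
  structure(list(L_img = L_img, L_gene = L_gene, L_hyb = L_hyb,
                 total = config$lambda1 * L_img + config$lambda2 * L_gene +
                   L_hyb),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.6g (img %.6g, gene %.6g, hyb %.6g)\n",
              x$total, x$L_img, x$L_gene, x$L_hyb))
  invisible(x)
}

# gradients of the total loss w.r.t. every weight; img_target is the clean
# image-branch target when recon_img_target = "image"
model_backward <- function(bundle, target, params, config, img_target = NULL) {
  fwd <- bundle$.fwd
  ai <- fwd$ai
  it <- if (config$recon_img_target == "image") img_target else target
  dR_img <- 2 * config$lambda1 * (bundle$recon_img - it) / length(it)
  dR_gene <- 2 * config$lambda2 * (bundle$recon_gene - target) / length(target)
  dR_hyb <- 2 * (bundle$recon_hyb - target) / length(target)
  bh <- ae_backward(dR_hyb, NULL, fwd$hyb, params$hyb, ai)
  latent <- ncol(bundle$z_img)
  dZ_img <- bh$dInput[, seq_len(latent), drop = FALSE]
  dZ_gene <- bh$dInput[, latent + seq_len(latent), drop = FALSE]
  bi <- ae_backward(dR_img, dZ_img, fwd$img, params$img, ai)
  bg <- ae_backward(dR_gene, dZ_gene, fwd$gene, params$gene, ai)
  list(img = bi$grads, gene = bg$grads, hyb = bh$grads)
}
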