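#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001 and
#' weight decay 1e-4, 1,000 epochs of full-graph training, gradients clipped
#' to a maximum global norm of 5.
#'
#' @param lr learning rate (> 0).
#' @param epochs number of full-graph epochs (>= 1).
#' @param grad_clip_norm maximum global gradient norm (> 0).
#' @param weight_decay Adam L2 weight decay.
#' @param input_corruption denoising-autoencoder input corruption: the
#'   fraction of encoder-input entries randomly zeroed (with inverted-dropout
#'   rescaling) at every epoch, in `[0, 1)`. The reconstruction target is
#'   never corrupted. Default 0.5, on the order of the dropout rate the
#'   denoiser is meant to remove; set 0 to train on clean inputs.
#' @param seed integer seed for weight initialization and the corruption
#'   stream.
#' @param log_every print a progress line every this many epochs (0 = silent).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 1000L, grad_clip_norm = 5,
                         weight_decay = 1e-4, input_corruption = 0.5,
                         seed = 1L, log_every = 0L) {
  if (lr <= 0) stopf("lr must be > 0")
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (grad_clip_norm <= 0) stopf("grad_clip_norm must be > 0")
  if (input_corruption < 0 || input_corruption >= 1) {
    stopf("input_corruption must be in [0, 1)")
  }
  structure(list(lr = lr, epochs = as.integer(epochs),
                 grad_clip_norm = grad_clip_norm,
                 weight_decay = weight_decay,
                 input_corruption = input_corruption, optimizer = "adam",
                 seed = as.integer(seed), log_every = as.integer(log_every)),
            class = "train_config")
}

#' Seed every random stream used by the package
#'
#' All randomness (weight initialization, any sampling in the simulators and
#' clusterers) flows through R's global Mersenne-Twister stream; this pins it.
#'
#' @param seed integer.
#' @return `seed`, invisibly.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

adam_init <- function(params) {
  list(m = tree_map(function(w) w * 0, params),
       v = tree_map(function(w) w * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- tree_map(function(g, w) g + weight_decay * w, grads, params)
  }
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(w, m, v) {
    w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Train the hybrid graph transformer
#'
#' Full-graph self-supervised training: every epoch runs one forward pass,
#' the weighted reconstruction loss, backpropagation, global-norm gradient
#' clipping, and one Adam step. Fixed seed gives a bit-stable loss history on
#' the same platform.
#'
#' @param dataset a preprocessed `spatial_dataset` (layer `"norm"` present).
#' @param features a standardized `feature_matrix` (see
#'   [standardize_features()]).
#' @param graph a `spatial_graph` over the same cells.
#' @param model_config a [model_config()]; defaults are derived from the data
#'   shapes when `NULL`.
#' @param config a [train_config()].
#' @return A `train_fit`: `params` (trained weights), `history` (one row per
#'   epoch: losses and post-clip gradient norm), `model_config`, `config`.
#' @export
train <- function(dataset, features, graph, model_config = NULL,
                  config = train_config()) {
  X <- get_layer(dataset, "norm")
  Fm <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (is.null(model_config)) {
    model_config <- stfuse::model_config(gene_dim = ncol(X),
                                         img_dim = ncol(Fm))
  }
  set_global_seed(config$seed)
  params <- init_model(model_config)
  run_training(params, X, Fm, graph, model_config, config)
}

# the gene encoder consumes per-gene standardized values so the attention
# softmax starts in its linear regime; the loss target stays the normalized
# log layer itself
gene_encoder_input <- function(X) standardize_features(as.matrix(X))

# optimization loop shared by train() and stfuse(); params already
# initialized and the RNG already seeded (the corruption masks draw from it)
run_training <- function(params, X, Fm, graph, model_config, config) {
  ai <- attention_index(graph)
  state <- adam_init(params)
  Xin <- gene_encoder_input(X)
  p_cor <- config$input_corruption
  hist <- data.frame(epoch = seq_len(config$epochs), L_img = NA_real_,
                     L_gene = NA_real_, L_hyb = NA_real_, total = NA_real_,
                     grad_norm = NA_real_)
  for (ep in seq_len(config$epochs)) {
    if (p_cor > 0) {
      Xe <- Xin * (matrix(stats::runif(length(Xin)) >= p_cor,
                          nrow(Xin)) / (1 - p_cor))
      Fe <- Fm * (matrix(stats::runif(length(Fm)) >= p_cor,
                         nrow(Fm)) / (1 - p_cor))
    } else {
      Xe <- Xin
      Fe <- Fm
    }
    bundle <- model_forward(Xe, Fe, graph, params, model_config, ai = ai)
    lb <- compute_loss(bundle, X, model_config, img_target = Fm)
    if (!is.finite(lb$total)) {
      stopf("non-finite loss at epoch %d (last finite total: %s)", ep,
            format(utils::tail(stats::na.omit(hist$total), 1L)))
    }
    grads <- model_backward(bundle, X, params, model_config, img_target = Fm)
    gn <- tree_global_norm(grads)
    if (gn > config$grad_clip_norm) {
      grads <- tree_map(function(g) g * (config$grad_clip_norm / gn), grads)
    }
    hist[ep, 2:6] <- c(lb$L_img, lb$L_gene, lb$L_hyb, lb$total,
                       tree_global_norm(grads))
    upd <- adam_step(params, grads, state, config$lr, config$weight_decay)
    params <- upd$params
    state <- upd$state
    if (config$log_every > 0L && ep %% config$log_every == 0L) {
      message(sprintf("epoch %d: total %.6g (img %.6g, gene %.6g, hyb %.6g)",
                      ep, lb$total, lb$L_img, lb$L_gene, lb$L_hyb))
    }
  }
  structure(list(params = params, history = hist,
                 model_config = model_config, config = config),
            class = "train_fit")
}

#' Save / load a model checkpoint
#'
#' One file holding the trained weights together with both configurations and
#' the seed, so a fit can be reloaded and re-applied to data of the same
#' shape.
#'
#' @param fit a `train_fit` or `stfuse` object.
#' @param path checkpoint file path.
#' @return `load_checkpoint` returns the stored list.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params, model_config = fit$model_config,
               config = fit$config, seed = fit$config$seed,
               history = fit$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  readRDS(path)
}
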