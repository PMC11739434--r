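make_tiny <- function(n = 6, g = 4, f = 5, radius = 5, seed = 7,
                      n_heads = 1L) {
  set_global_seed(seed)
  list(X = matrix(rnorm(n * g), n, g),
       Fm = matrix(rnorm(n * f), n, f),
       graph = build_radius_graph(cbind(runif(n, 0, 10), runif(n, 0, 10)),
                                  radius),
       cfg = model_config(g, f, hidden_dim = 4L, latent_dim = 2L,
                          n_heads = n_heads))
}

test_that("neighbor attention equals the dense masked-softmax oracle", {
  for (seed in 1:5) {
    set_global_seed(seed)
    n <- sample(4:10, 1)
    H <- matrix(rnorm(n * 5), n, 5)
    graph <- build_radius_graph(cbind(runif(n, 0, 10), runif(n, 0, 10)), 5)
    ai <- stfuse:::attention_index(graph)
    for (heads in c(1L, 2L)) {
      layer <- stfuse:::init_attn_layer(5L, 6L, heads)
      for (act in c("elu", "identity")) {
        got <- stfuse:::attn_forward(H, ai, layer, act)$out
        want <- dense_attention_oracle(H, graph, layer, act)
        expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
      }
    }
  }
})

test_that("with no edges attention reduces to a per-cell dense layer", {
  set_global_seed(19)
  n <- 5
  H <- matrix(rnorm(n * 3), n, 3)
  graph <- build_radius_graph(cbind(seq(0, 400, 100), rep(0, n)), 1)
  expect_identical(nrow(graph$edges), 0L)
  ai <- stfuse:::attention_index(graph)
  layer <- stfuse:::init_attn_layer(3L, 4L, 1L)
  got <- stfuse:::attn_forward(H, ai, layer, "elu")$out
  # singleton softmax = 1, so output is elu(H Wv + b) rowwise
  want <- stfuse:::elu(H %*% layer$heads[[1]]$Wv + rep(layer$b, each = n))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("identical inputs give identical attention outputs on any graph", {
  set_global_seed(20)
  n <- 7
  H <- matrix(rep(rnorm(3), each = n), n, 3)
  graph <- build_radius_graph(cbind(runif(n, 0, 3), runif(n, 0, 3)), 2)
  ai <- stfuse:::attention_index(graph)
  layer <- stfuse:::init_attn_layer(3L, 4L, 1L)
  out <- stfuse:::attn_forward(H, ai, layer, "elu")$out
  expect_equal(out, matrix(rep(out[1, ], each = n), n, 4), tolerance = 1e-12)
})

test_that("forward pass honors the shape contract and is deterministic", {
  tiny <- make_tiny(n = 9, g = 6, f = 4, n_heads = 2L)
  set_global_seed(1)
  params <- init_model(tiny$cfg)
  b1 <- model_forward(tiny$X, tiny$Fm, tiny$graph, params, tiny$cfg)
  for (z in list(b1$z_img, b1$z_gene, b1$z_hyb)) {
    expect_identical(dim(z), c(9L, 2L))
  }
  for (r in list(b1$recon_img, b1$recon_gene, b1$recon_hyb)) {
    expect_identical(dim(r), c(9L, 6L))
  }
  b2 <- model_forward(tiny$X, tiny$Fm, tiny$graph, params, tiny$cfg)
  expect_identical(b1$recon_hyb, b2$recon_hyb)
  expect_identical(b1$z_hyb, b2$z_hyb)
})

test_that("an isolated single cell equals composed per-cell dense layers", {
  set_global_seed(22)
  cfg <- model_config(3L, 2L, hidden_dim = 4L, latent_dim = 2L)
  params <- init_model(cfg)
  graph <- build_radius_graph(cbind(0, 0), 1)
  X <- matrix(rnorm(3), 1, 3)
  Fm <- matrix(rnorm(2), 1, 2)
  b <- model_forward(X, Fm, graph, params, cfg)
  dense <- function(H, layer, act) {
    M <- H %*% layer$heads[[1]]$Wv + rep(layer$b, each = nrow(H))
    if (act == "elu") stfuse:::elu(M) else M
  }
  ae <- function(H, p) {
    z <- dense(dense(H, p$enc1, "elu"), p$enc2, "elu")
    list(z = z, recon = dense(dense(z, p$dec1, "elu"), p$dec2, "identity"))
  }
  oi <- ae(Fm, params$img)
  og <- ae(X, params$gene)
  oh <- ae(cbind(oi$z, og$z), params$hyb)
  expect_equal(b$z_hyb, oh$z, tolerance = 1e-6)
  expect_equal(b$recon_hyb, oh$recon, tolerance = 1e-6)
  expect_equal(b$recon_img, oi$recon, tolerance = 1e-6)
})

test_that("the weighted loss matches hand-summed arithmetic", {
  set_global_seed(23)
  target <- matrix(rnorm(20), 5, 4)
  bundle <- structure(list(recon_img = matrix(rnorm(20), 5, 4),
                           recon_gene = matrix(rnorm(20), 5, 4),
                           recon_hyb = matrix(rnorm(20), 5, 4)),
                      class = "embedding_bundle")
  cfg <- model_config(4L, 3L, lambda1 = 0.3, lambda2 = 0.7)
  lb <- compute_loss(bundle, target, cfg)
  hand <- function(A, B) sum((A - B)^2) / 20
  expect_equal(lb$L_img, hand(bundle$recon_img, target), tolerance = 1e-9)
  expect_equal(lb$total,
               0.3 * hand(bundle$recon_img, target) +
                 0.7 * hand(bundle$recon_gene, target) +
                 hand(bundle$recon_hyb, target),
               tolerance = 1e-9)
  # perfect reconstruction gives exactly zero
  perfect <- structure(list(recon_img = target, recon_gene = target,
                            recon_hyb = target), class = "embedding_bundle")
  expect_identical(compute_loss(perfect, target, cfg)$total, 0)
  # lambda nulling isolates the hybrid term
  cfg0 <- model_config(4L, 3L, lambda1 = 0, lambda2 = 0)
  lb0 <- compute_loss(bundle, target, cfg0)
  expect_identical(lb0$total, lb0$L_hyb)
  expect_gte(lb0$total, 0)
})

test_that("permuting cells permutes every output row identically", {
  set_global_seed(24)
  n <- 8
  X <- matrix(rnorm(n * 5), n, 5)
  Fm <- matrix(rnorm(n * 3), n, 3)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  cfg <- model_config(5L, 3L, hidden_dim = 4L, latent_dim = 2L)
  set_global_seed(2)
  params <- init_model(cfg)
  b <- model_forward(X, Fm, build_radius_graph(coords, 5), params, cfg)
  set.seed(25)
  perm <- sample(n)
  gp <- build_radius_graph(coords[perm, ], 5)
  bp <- model_forward(X[perm, ], Fm[perm, ], gp, params, cfg)
  expect_equal(bp$z_hyb, b$z_hyb[perm, ], tolerance = 1e-8)
  expect_equal(bp$recon_hyb, b$recon_hyb[perm, ], tolerance = 1e-8)
  expect_equal(bp$recon_img, b$recon_img[perm, ], tolerance = 1e-8)
})

test_that("backprop matches finite differences on a tiny model", {
  tiny <- make_tiny(n = 6, g = 4, f = 5, seed = 42, n_heads = 2L)
  set_global_seed(3)
  params <- init_model(tiny$cfg)
  lossfn <- function(p) {
    b <- model_forward(tiny$X, tiny$Fm, tiny$graph, p, tiny$cfg)
    compute_loss(b, tiny$X, tiny$cfg)$total
  }
  b <- model_forward(tiny$X, tiny$Fm, tiny$graph, params, tiny$cfg)
  grads <- stfuse:::model_backward(b, tiny$X, params, tiny$cfg)
  eps <- 1e-5
  set.seed(4)
  for (br in c("img", "gene", "hyb")) {
    for (ly in c("enc1", "enc2", "dec1", "dec2")) {
      for (w in c("Wq", "Wk", "Wv")) {
        h <- sample(2, 1)
        W <- params[[br]][[ly]]$heads[[h]][[w]]
        idx <- cbind(sample(nrow(W), 1), sample(ncol(W), 1))
        p1 <- params; p1[[br]][[ly]]$heads[[h]][[w]][idx] <- W[idx] + eps
        p2 <- params; p2[[br]][[ly]]$heads[[h]][[w]][idx] <- W[idx] - eps
        fd <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        an <- grads[[br]][[ly]]$heads[[h]][[w]][idx]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
      }
      p1 <- params; p1[[br]][[ly]]$b[1] <- p1[[br]][[ly]]$b[1] + eps
      p2 <- params; p2[[br]][[ly]]$b[1] <- p2[[br]][[ly]]$b[1] - eps
      fd <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      an <- grads[[br]][[ly]]$b[1]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
    }
  }
})

test_that("config validation rejects bad dimensions and weights", {
  expect_error(model_config(0L, 5L), ">= 1")
  expect_error(model_config(4L, 5L, lambda1 = -0.1), ">= 0")
  expect_error(model_config(4L, 5L, hidden_dim = 6L, n_heads = 4L),
               "divide")
})
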