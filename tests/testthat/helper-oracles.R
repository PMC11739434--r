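# independent brute-force oracles used across the suite

# O(n^2) pair-counting ARI: count agreeing/disagreeing pairs directly
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  n11 <- sum(same_a[ut] & same_b[ut])
  a_pairs <- sum(same_a[ut])
  b_pairs <- sum(same_b[ut])
  total <- choose(n, 2)
  expected <- a_pairs * b_pairs / total
  max_index <- (a_pairs + b_pairs) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# all-pairs radius graph
radius_graph_oracle <- function(coords, radius) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# dense masked-softmax attention over {i} + neighbors(i)
dense_attention_oracle <- function(H, graph, layer, activation = "elu") {
  n <- nrow(H)
  A <- diag(n)
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1]
      j <- graph$edges[e, 2]
      A[i, j] <- A[j, i] <- 1
    }
  }
  n_heads <- length(layer$heads)
  dh <- ncol(layer$heads[[1]]$Wv)
  Ms <- NULL
  for (h in seq_len(n_heads)) {
    p <- layer$heads[[h]]
    S <- (H %*% p$Wq) %*% t(H %*% p$Wk) / sqrt(dh)
    S[A == 0] <- -Inf
    W <- exp(S - apply(S, 1, max))
    W <- W / rowSums(W)
    Ms <- cbind(Ms, W %*% (H %*% p$Wv))
  }
  M <- Ms + rep(layer$b, each = n)
  if (activation == "elu") pmax(M, 0) + expm1(pmin(M, 0)) else M
}

# per-pixel index-mapping patch oracle (triple loop)
patch_oracle <- function(pixels, x, y, size) {
  H <- dim(pixels)[1]
  W <- dim(pixels)[2]
  half <- size / 2
  out <- array(0, c(3, size, size))
  for (py in 0:(size - 1)) {
    for (px in 0:(size - 1)) {
      r <- y - half + py
      c <- x - half + px
      if (r >= 0 && r < H && c >= 0 && c < W) {
        out[, py + 1, px + 1] <- pixels[r + 1, c + 1, ]
      }
    }
  }
  out
}

# naive per-pixel counting oracle for the texture feature vector
texture_feature_oracle <- function(patch, n_bins, grid) {
  S <- dim(patch)[2]
  cuts <- floor(seq(0, S, length.out = grid + 1))
  feats <- numeric(0)
  for (ch in 1:3) {
    for (gy in seq_len(grid)) {
      for (gx in seq_len(grid)) {
        h <- numeric(n_bins)
        npix <- 0
        for (r in (cuts[gy] + 1):cuts[gy + 1]) {
          for (c in (cuts[gx] + 1):cuts[gx + 1]) {
            b <- min(floor(patch[ch, r, c] * n_bins / 256), n_bins - 1)
            h[b + 1] <- h[b + 1] + 1
            npix <- npix + 1
          }
        }
        feats <- c(feats, h / npix)
      }
    }
  }
  for (ch in 1:3) feats <- c(feats, mean(patch[ch, , ]), sd(patch[ch, , ]))
  gray <- (patch[1, , ] + patch[2, , ] + patch[3, , ]) / 3
  h <- numeric(n_bins)
  cnt <- 0
  for (r in 1:(S - 1)) {
    for (c in 1:(S - 1)) {
      dx <- gray[r, c + 1] - gray[r, c]
      dy <- gray[r + 1, c] - gray[r, c]
      m <- sqrt(dx^2 + dy^2)
      b <- min(floor(m * n_bins / (256 * sqrt(2))), n_bins - 1)
      h[b + 1] <- h[b + 1] + 1
      cnt <- cnt + 1
    }
  }
  c(feats, h / cnt)
}

# small random fixtures
random_dataset <- function(n = 20, g = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rpois(n * g, 3), n, g)
  spatial_dataset(X, cbind(runif(n, 0, 100), runif(n, 0, 100)),
                  layers = list(raw = X))
}

random_patchset <- function(n = 4, S = 8, seed = 1) {
  set.seed(seed)
  structure(list(patches = array(sample(0:255, n * 3 * S * S, TRUE),
                                 c(n, 3, S, S)), size = S),
            class = "patch_set")
}
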