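test_that("contingency table is an exact cross-tabulation", {
  ct <- contingency(c(0, 0, 1), c(1, 1, 0))
  expect_identical(unname(ct$counts), matrix(c(0L, 1L, 2L, 0L), 2, 2))
  expect_identical(ct$n, 3L)
  ct2 <- contingency(c("a", "b", "a"), c("a", "b", "a"))
  expect_identical(unname(diag(ct2$counts)), c(2L, 1L))
  expect_error(contingency(1:3, 1:4), "length")
  # random labelings against a per-sample tally
  set.seed(50)
  for (rep in 1:5) {
    a <- sample(0:2, 30, TRUE)
    b <- sample(0:3, 30, TRUE)
    ct <- contingency(a, b)
    for (i in 0:2) for (j in 0:3) {
      expect_identical(ct$counts[as.character(i), as.character(j)],
                       sum(a == i & b == j))
    }
    expect_identical(sum(ct$counts), 30L)
  }
})

test_that("ARI reproduces hand-evaluated cases", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5,
               tolerance = 1e-12)
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_identical(adjusted_rand_index(c("x", "x", "y"), c("b", "b", "a")), 1)
  expect_error(adjusted_rand_index(1, 1), "at least 2")
})

test_that("ARI matches the pair-counting oracle on random partitions", {
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    a <- sample(0:(sample(2:5, 1) - 1), n, TRUE)
    b <- sample(0:(sample(2:5, 1) - 1), n, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
                 tolerance = 1e-12)
    # symmetry and label-renaming invariance
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 adjusted_rand_index(max(a) - a, b), tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent library implementation", {
  set.seed(52)
  for (rep in 1:10) {
    a <- sample(0:3, 40, TRUE)
    b <- sample(0:2, 40, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("clustering recovers well-separated blobs and is seeded", {
  set.seed(53)
  Z <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
             matrix(rnorm(100, 8, 0.2), 50, 2))
  truth <- rep(0:1, each = 50)
  for (method in c("gmm", "kmeans")) {
    lab <- cluster_embeddings(Z, 2, seed = 1, method = method)
    expect_identical(adjusted_rand_index(lab, truth), 1)
    expect_true(all(lab %in% 0:1))
  }
  expect_identical(cluster_embeddings(Z, 1), rep(0L, 100))
  expect_identical(cluster_embeddings(Z, 2, seed = 7),
                   cluster_embeddings(Z, 2, seed = 7))
  expect_error(cluster_embeddings(Z[1:3, ], 5), "exceeds")
})

test_that("rank_genes puts a perfectly separating gene on top", {
  set.seed(54)
  n <- 100
  labels <- rep(c("A", "B"), each = 50)
  X <- matrix(rnorm(n * 10, 1, 0.3), n, 10)
  X <- pmax(X, 0)
  X[labels == "A", 3] <- 10
  X[labels == "B", 3] <- 0
  tab <- rank_genes(X, labels, gene_names = paste0("g", 1:10))
  topA <- tab[tab$cluster == "A", ][1, ]
  expect_identical(topA$gene, "g3")
  expect_true(topA$significant)
  expect_gt(topA$lfc, 0)
  # adjusted p never below raw p, counts match the threshold rule
  expect_true(all(tab$padj >= tab$pval - 1e-15))
  counts <- attr(tab, "deg_counts")
  for (cl in c("A", "B")) {
    expect_identical(unname(counts[cl]),
                     sum(tab$significant[tab$cluster == cl]))
  }
})

test_that("rank_genes skips singleton clusters with a warning", {
  X <- matrix(rpois(33, 3), 11, 3)
  labels <- c(rep("big", 10), "tiny")
  expect_warning(tab <- rank_genes(X, labels), "tiny")
  expect_identical(unique(tab$cluster), "big")
})

test_that("null DEG calibration stays near the FDR level", {
  set.seed(55)
  fractions <- numeric(20)
  for (rep in 1:20) {
    X <- log1p(matrix(rnbinom(200 * 50, mu = 2, size = 2), 200, 50))
    labels <- sample(rep(0:3, each = 50))
    tab <- rank_genes(X, labels, alpha = 0.05, lfc_min = 0.25)
    fractions[rep] <- mean(tapply(tab$significant, tab$cluster, mean))
  }
  expect_lte(mean(fractions), 0.05)
})

test_that("paired raw-vs-enhanced test matches the closed form", {
  set.seed(56)
  raw <- rnorm(30, 1)
  enh <- raw + rnorm(30, 0.3, 0.5)
  got <- compare_raw_enhanced(raw, enh)
  d <- enh - raw
  t_hand <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(got$t, t_hand, tolerance = 1e-9)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = 29), tolerance = 1e-9)
  expect_identical(got$direction, if (mean(d) > 0) "up" else "down")
})

test_that("degenerate paired comparisons follow the documented rules", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_raw_enhanced(x, x)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_identical(same$direction, "none")
  shift <- compare_raw_enhanced(x, x + 1)
  expect_identical(shift$direction, "up")
  expect_lt(shift$p, 1e-6)
  expect_error(compare_raw_enhanced(1:2, 2:3), "at least 3")
  # region mask restricts the test
  masked <- compare_raw_enhanced(c(x, 9), c(x + 1, 9),
                                 region_mask = c(rep(TRUE, 5), FALSE))
  expect_identical(masked$n, 5L)
})

test_that("2-D projection is deterministic and keeps blobs separable", {
  set.seed(57)
  Z <- rbind(matrix(rnorm(300, 0, 0.5), 30, 10),
             matrix(rnorm(300, 4, 0.5), 30, 10))
  truth <- rep(c(0, 1), each = 30)
  Y <- project_2d(Z, seed = 1)
  expect_identical(dim(Y), c(60L, 2L))
  expect_identical(Y, project_2d(Z, seed = 1))
  fit <- MASS::lda(Y, grouping = truth)
  acc <- mean(predict(fit, Y)$class == truth)
  expect_gt(acc, 0.95)
  expect_error(project_2d(Z[1:5, ]), "at least 10")
})
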