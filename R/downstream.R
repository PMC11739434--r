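#' Denoised ("enhanced") expression from a trained model
#'
#' A forward pass of the trained model; the hybrid reconstruction, clipped
#' below at zero (normalized log expression is non-negative), is the enhanced
#' expression and is stored in layer `"enhanced"`.
#'
#' @param fit a `stfuse` or `train_fit` object (or a loaded checkpoint).
#' @param dataset a preprocessed `spatial_dataset`.
#' @param features a standardized `feature_matrix`.
#' @param graph a `spatial_graph`.
#' @return The dataset with layer `"enhanced"` set.
#' @export
enhance_expression <- function(fit, dataset, features, graph) {
  X <- get_layer(dataset, "norm")
  Fm <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  cfg <- fit$model_config
  if (ncol(X) != cfg$gene_dim || ncol(Fm) != cfg$img_dim) {
    stopf("data shapes (%d genes, %d image dims) do not match the checkpoint config (%d, %d)",
          ncol(X), ncol(Fm), cfg$gene_dim, cfg$img_dim)
  }
  bundle <- model_forward(gene_encoder_input(X), Fm, graph, fit$params, cfg)
  set_layer(dataset, "enhanced", pmax(bundle$recon_hyb, 0))
}

#' Cluster per-cell embeddings into k groups
#'
#' Default is a Gaussian-mixture model (common-covariance, via mclust) with a
#' fixed, known k, matching benchmark practice for spatial-domain
#' identification; k-means is available as an alternative. Deterministic
#' given the seed.
#'
#' @param Z cells x latent matrix.
#' @param k number of clusters (>= 1, <= cells).
#' @param seed integer seed.
#' @param method `"gmm"` (default) or `"kmeans"`.
#' @return Integer labels in `[0, k)`, one per cell.
#' @export
cluster_embeddings <- function(Z, k, seed = 1L, method = c("gmm", "kmeans")) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  if (k > nrow(Z)) stopf("k = %d exceeds the number of cells (%d)", k, nrow(Z))
  if (k == 1L) return(rep(0L, nrow(Z)))
  set_global_seed(seed)
  labels <- if (method == "gmm") {
    fit <- tryCatch(
      mclust::Mclust(Z, G = k, modelNames = "EEE", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) NULL else fit$classification
  } else NULL
  if (is.null(labels)) {
    labels <- stats::kmeans(Z, centers = k, nstart = 10L,
                            iter.max = 100L)$cluster
  }
  as.integer(labels) - 1L
}

#' Cross-tabulate two labelings
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A `contingency_table`: `counts` (K_A x K_B), `row_sums`,
#'   `col_sums`, `n`.
#' @export
contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stopf("labelings differ in length (%d vs %d)",
          length(labels_a), length(labels_b))
  }
  tab <- table(factor(labels_a), factor(labels_b))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  structure(list(counts = counts, row_sums = rowSums(counts),
                 col_sums = colSums(counts), n = length(labels_a)),
            class = "contingency_table")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table with binomial coefficients:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Equals 1 for identical
#' partitions, is symmetric, and is invariant to label renaming; values range
#' from about -1 to 1, with 0 the chance level.
#'
#' @param labels_a,labels_b equal-length label vectors (n >= 2).
#' @return A single number.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  ct <- contingency(labels_a, labels_b)
  if (ct$n < 2L) stopf("ARI needs at least 2 samples (got %d)", ct$n)
  sum_ij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_sums, 2))
  sum_b <- sum(choose(ct$col_sums, 2))
  expected <- sum_a * sum_b / choose(ct$n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' One-vs-rest marker-gene (DEG) test per cluster
#'
#' For each cluster, each gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test; p-values are Benjamini-Hochberg adjusted within
#' cluster. The log fold change is `log2` of the ratio of group means on the
#' expm1 scale (values are assumed log1p-normalized). A gene is a DEG of a
#' cluster when `padj < alpha` and `|lfc| >= lfc_min`.
#'
#' @param X cells x genes matrix (a log-normalized or enhanced layer).
#' @param labels per-cell cluster labels.
#' @param alpha FDR level (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 0.25).
#' @param gene_names optional gene names.
#' @return A `deg_table` data.frame with columns cluster, gene, lfc, stat,
#'   pval, padj, significant — sorted by adjusted p within cluster. Per-cluster
#'   DEG counts are in `attr(, "deg_counts")`.
#' @export
rank_genes <- function(X, labels, alpha = 0.05, lfc_min = 0.25,
                       gene_names = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    stopf("%d labels for %d cells", length(labels), nrow(X))
  }
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stopf("rank_genes needs at least 2 clusters")
  if (is.null(gene_names)) gene_names <- colnames(X)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(X)))
  out <- vector("list", length(clusters))
  eps <- 1e-9
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    ing <- labels == cl
    if (sum(ing) < 2L) {
      warnf("cluster '%s' has fewer than 2 cells; skipped", cl)
      next
    }
    Xin <- X[ing, , drop = FALSE]
    Xout <- X[!ing, , drop = FALSE]
    stat <- pval <- lfc <- numeric(ncol(X))
    for (g in seq_len(ncol(X))) {
      wt <- suppressWarnings(stats::wilcox.test(Xin[, g], Xout[, g],
                                                exact = FALSE))
      stat[g] <- unname(wt$statistic)
      pval[g] <- wt$p.value
      lfc[g] <- log2((expm1(mean(Xin[, g])) + eps) /
                     (expm1(mean(Xout[, g])) + eps))
    }
    pval[is.na(pval)] <- 1
    padj <- stats::p.adjust(pval, method = "BH")
    df <- data.frame(cluster = cl, gene = gene_names, lfc = lfc, stat = stat,
                     pval = pval, padj = padj,
                     significant = padj < alpha & abs(lfc) >= lfc_min,
                     stringsAsFactors = FALSE)
    out[[ci]] <- df[order(df$padj, df$pval), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  counts <- tapply(res$significant, res$cluster, sum)
  attr(res, "deg_counts") <- counts
  attr(res, "alpha") <- alpha
  attr(res, "lfc_min") <- lfc_min
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Paired comparison of raw vs enhanced expression of one gene
#'
#' Two-sided paired t-test on `enhanced - raw` over the selected cells,
#' reporting the statistic, p-value and the direction of the mean change.
#' When the paired differences have zero variance but a nonzero mean (an
#' exact shift), the p-value is reported as the smallest representable
#' positive double rather than failing.
#'
#' @param raw,enhanced equal-length per-cell values of one gene.
#' @param region_mask optional logical per-cell mask restricting the test to
#'   a tissue region.
#' @return list with `t`, `p`, `direction` (`"up"`, `"down"`, `"none"`),
#'   `mean_diff`, `n`.
#' @export
compare_raw_enhanced <- function(raw, enhanced, region_mask = NULL) {
  if (length(raw) != length(enhanced)) {
    stopf("raw and enhanced differ in length (%d vs %d)",
          length(raw), length(enhanced))
  }
  if (!is.null(region_mask)) {
    raw <- raw[region_mask]
    enhanced <- enhanced[region_mask]
  }
  n <- length(raw)
  if (n < 3L) stopf("need at least 3 selected cells (got %d)", n)
  d <- enhanced - raw
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, direction = "none", mean_diff = 0, n = n))
    }
    return(list(t = sign(md) * Inf, p = .Machine$double.xmin,
                direction = if (md > 0) "up" else "down",
                mean_diff = md, n = n))
  }
  tt <- stats::t.test(enhanced, raw, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       direction = if (md > 0) "up" else if (md < 0) "down" else "none",
       mean_diff = md, n = n)
}

#' Deterministic 2-D projection of embeddings for visualization
#'
#' A seeded principal-component projection onto the two leading axes, with
#' signs fixed so repeated calls are identical. (A linear projection is used
#' for full determinism; it preserves the separation of well-separated
#' clusters, which is all the package's figures rely on.)
#'
#' @param Z cells x latent matrix (n >= 10).
#' @param seed integer seed (recorded; the projection itself is
#'   deterministic).
#' @return cells x 2 matrix.
#' @export
project_2d <- function(Z, seed = 1L) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 10L) stopf("project_2d needs at least 10 cells")
  set_global_seed(seed)
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = 2L)
  Y <- pc$x[, 1:2, drop = FALSE]
  # fix sign: largest-magnitude loading of each axis is positive
  for (j in 1:2) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) Y[, j] <- -Y[, j]
  }
  unname(Y)
}
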