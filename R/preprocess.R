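#' Make gene names pairwise distinct
#'
#' First occurrences are kept unchanged; the k-th duplicate (k >= 2) gets the
#' suffix `-(k-1)`. A proposed suffixed name that collides with any other
#' original or already-assigned name is bumped to the next free suffix, so the
#' output is always pairwise distinct.
#'
#' @param names character vector.
#' @return character vector of the same length, pairwise distinct.
#' @export
make_names_unique <- function(names) {
  names <- as.character(names)
  out <- character(length(names))
  taken <- new.env(parent = emptyenv())
  # original names reserve their spelling so a later first occurrence survives
  originals <- new.env(parent = emptyenv())
  for (nm in names) assign(nm, TRUE, envir = originals)
  counter <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    nm <- names[i]
    if (!exists(nm, envir = taken, inherits = FALSE)) {
      out[i] <- nm
      assign(nm, TRUE, envir = taken)
      next
    }
    k <- if (exists(nm, envir = counter, inherits = FALSE)) {
      get(nm, envir = counter)
    } else 1L
    repeat {
      cand <- paste0(nm, "-", k)
      k <- k + 1L
      if (!exists(cand, envir = taken, inherits = FALSE) &&
          !exists(cand, envir = originals, inherits = FALSE)) break
    }
    assign(nm, k, envir = counter)
    out[i] <- cand
    assign(cand, TRUE, envir = taken)
  }
  out
}

#' Scale each cell to a common total
#'
#' Every row (cell) with a nonzero sum is rescaled to sum to `target_sum`;
#' all-zero rows are left untouched. Idempotent.
#'
#' @param X non-negative cells x genes matrix.
#' @param target_sum positive per-cell total (default 1e4).
#' @return Matrix of the same shape.
#' @export
normalize_total <- function(X, target_sum = 1e4) {
  X <- as.matrix(X)
  if (any(X < 0)) stopf("normalize_total: matrix has negative entries")
  if (!is.numeric(target_sum) || target_sum <= 0) {
    stopf("target_sum must be a positive scalar")
  }
  rs <- rowSums(X)
  scale <- ifelse(rs > 0, target_sum / rs, 1)
  X * scale
}

#' Elementwise log(1 + x)
#'
#' @param X non-negative matrix.
#' @return log1p-transformed matrix (natural log; 0 maps to 0).
#' @export
log1p_transform <- function(X) {
  if (any(X < 0)) stopf("log1p_transform: matrix has negative entries")
  log1p(X)
}

#' Standard expression preprocessing
#'
#' Deduplicates gene names, then per-cell total normalization, then log1p —
#' in that fixed order — writing the result to layer `"norm"`. Optionally
#' keeps only the `hvg_top_k` genes of highest variance (computed on the
#' log-normalized values), off by default.
#'
#' @param ds a `spatial_dataset` (layer `"raw"` used if present, else the
#'   expression matrix).
#' @param target_sum per-cell total after normalization (default 1e4).
#' @param hvg_top_k optional integer; subset to this many top-variance genes.
#' @return The dataset with gene names deduplicated and layer `"norm"` set.
#' @export
preprocess_dataset <- function(ds, target_sum = 1e4, hvg_top_k = NULL) {
  ds$gene_names <- make_names_unique(ds$gene_names)
  X <- if ("raw" %in% names(ds$layers)) ds$layers$raw else ds$expression
  norm <- log1p_transform(normalize_total(X, target_sum))
  if (!is.null(hvg_top_k)) {
    hvg_top_k <- as.integer(hvg_top_k)
    if (hvg_top_k < 1L || hvg_top_k > ncol(norm)) {
      stopf("hvg_top_k must be in [1, %d]", ncol(norm))
    }
    v <- apply(norm, 2L, stats::var)
    keep <- sort(order(v, decreasing = TRUE)[seq_len(hvg_top_k)])
    ds$expression <- ds$expression[, keep, drop = FALSE]
    ds$gene_names <- ds$gene_names[keep]
    ds$layers <- lapply(ds$layers, function(l) l[, keep, drop = FALSE])
    norm <- norm[, keep, drop = FALSE]
  }
  set_layer(ds, "norm", norm)
}
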