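#' Built-in deterministic texture features for one patch
#'
#' Concatenates (a) per-channel intensity histograms over a `grid` x `grid`
#' spatial partition of the patch, (b) per-channel mean and standard
#' deviation, and (c) a gradient-magnitude histogram of the grayscale patch.
#' Each histogram is normalized to sum 1. Output length is
#' `3 * n_bins * grid^2 + 6 + n_bins` (454 at the defaults). Seedless and
#' fully deterministic.
#'
#' @param patch 3 x S x S array with values in \[0, 255\].
#' @param n_bins histogram bins (default 16).
#' @param grid spatial partition per side (default 3).
#' @return numeric feature vector.
#' @export
builtin_texture_features <- function(patch, n_bins = 16L, grid = 3L) {
  d <- dim(patch)
  if (length(d) != 3L || d[1L] != 3L) stopf("patch must be a 3 x S x S array")
  S <- d[2L]
  n_bins <- as.integer(n_bins)
  grid <- as.integer(grid)
  # block boundaries: grid near-equal contiguous slices
  cuts <- floor(seq(0L, S, length.out = grid + 1L))
  feats <- numeric(0)
  for (ch in 1:3) {
    plane <- patch[ch, , ]
    bin <- pmin(floor(plane * n_bins / 256), n_bins - 1L)
    for (gy in seq_len(grid)) {
      for (gx in seq_len(grid)) {
        blk <- bin[(cuts[gy] + 1L):cuts[gy + 1L],
                   (cuts[gx] + 1L):cuts[gx + 1L]]
        h <- tabulate(blk + 1L, n_bins)
        feats <- c(feats, h / length(blk))
      }
    }
  }
  for (ch in 1:3) {
    plane <- patch[ch, , ]
    feats <- c(feats, mean(plane), stats::sd(plane))
  }
  gray <- (patch[1L, , ] + patch[2L, , ] + patch[3L, , ]) / 3
  if (S >= 2L) {
    dx <- gray[1:(S - 1L), 2:S] - gray[1:(S - 1L), 1:(S - 1L)]
    dy <- gray[2:S, 1:(S - 1L)] - gray[1:(S - 1L), 1:(S - 1L)]
    m <- sqrt(dx^2 + dy^2)
  } else {
    m <- 0
  }
  gmax <- 256 * sqrt(2)
  gbin <- pmin(floor(m * n_bins / gmax), n_bins - 1L)
  gh <- tabulate(gbin + 1L, n_bins)
  c(feats, gh / length(gbin))
}

#' Construct the built-in texture feature extractor
#'
#' A `feature_extractor` is the boundary behind which pretrained pathology
#' backbones (CTransPath/UNI-style) sit: any object with a `name`, an output
#' dimension `dim`, and an `extract(patches)` function mapping a cells x 3 x
#' S x S array to a cells x dim matrix in cell order.
#'
#' @param n_bins histogram bins.
#' @param grid spatial grid per side.
#' @return A `feature_extractor`.
#' @export
texture_extractor <- function(n_bins = 16L, grid = 3L) {
  n_bins <- as.integer(n_bins)
  grid <- as.integer(grid)
  structure(list(
    name = sprintf("builtin-texture(bins=%d,grid=%d)", n_bins, grid),
    dim = 3L * n_bins * grid * grid + 6L + n_bins,
    extract = function(patches) {
      n <- dim(patches)[1L]
      out <- matrix(0, n, 3L * n_bins * grid * grid + 6L + n_bins)
      for (i in seq_len(n)) {
        out[i, ] <- builtin_texture_features(patches[i, , , ], n_bins, grid)
      }
      out
    }), class = "feature_extractor")
}

#' Wrap precomputed per-cell embeddings as a feature extractor
#'
#' Adapter for features computed out-of-band by an external pretrained
#' backbone; ignores the patches and returns the stored matrix.
#'
#' @param values cells x dim matrix.
#' @param name recorded extractor name.
#' @return A `feature_extractor`.
#' @export
precomputed_extractor <- function(values, name = "precomputed") {
  values <- as.matrix(values)
  structure(list(name = name, dim = ncol(values),
                 extract = function(patches) {
                   if (dim(patches)[1L] != nrow(values)) {
                     stopf("precomputed features have %d rows for %d patches",
                           nrow(values), dim(patches)[1L])
                   }
                   values
                 }), class = "feature_extractor")
}

#' Extract per-cell image features from a patch set
#'
#' Runs the extractor in batches; batching never changes the values, only the
#' memory profile.
#'
#' @param patches a `patch_set`.
#' @param extractor a `feature_extractor` (default: built-in texture).
#' @param batch_size patches per batch.
#' @return A `feature_matrix`: list with `values` (cells x dim) and
#'   `extractor_name`.
#' @export
extract_features <- function(patches, extractor = texture_extractor(),
                             batch_size = 64L) {
  n <- dim(patches$patches)[1L]
  batch_size <- max(1L, as.integer(batch_size))
  starts <- seq(1L, n, by = batch_size)
  out <- matrix(0, n, extractor$dim)
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + batch_size - 1L, n)
    vals <- tryCatch(
      extractor$extract(patches$patches[idx, , , , drop = FALSE]),
      error = function(e) stopf("feature extraction failed on batch %d: %s",
                                bi, conditionMessage(e)))
    out[idx, ] <- vals
  }
  if (!all(is.finite(out))) stopf("extractor produced non-finite features")
  structure(list(values = out, extractor_name = extractor$name),
            class = "feature_matrix")
}

#' Standardize feature columns across cells
#'
#' Zero mean, unit variance per column; constant columns are set to zero.
#' Applied to every feature matrix before it enters the fusion model.
#'
#' @param features a `feature_matrix` or plain matrix.
#' @return Same type as the input, standardized.
#' @export
standardize_features <- function(features) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  Xc <- sweep(X, 2L, mu)
  keep <- sdv > 0
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, sdv[keep], "/")
  Xc[, !keep] <- 0
  if (inherits(features, "feature_matrix")) {
    features$values <- Xc
    features
  } else {
    Xc
  }
}

#' Load precomputed per-cell features from a CSV keyed by cell id
#'
#' The CSV must have a `cell_id` column; rows are re-aligned to the dataset
#' cell order, and any dataset cell missing from the file is an error.
#'
#' @param path CSV path.
#' @param dataset the `spatial_dataset` defining cell order.
#' @return A `feature_matrix` aligned to the dataset.
#' @export
load_precomputed_features <- function(path, dataset) {
  if (!file.exists(path)) stopf("feature file not found: %s", path)
  x <- read_matrix_csv(path, has_row_ids = TRUE)
  missing <- setdiff(dataset$cell_ids, rownames(x))
  if (length(missing)) {
    stopf("feature file is missing cells: %s",
          paste(utils::head(missing, 10L), collapse = ", "))
  }
  vals <- unname(x[dataset$cell_ids, , drop = FALSE])
  structure(list(values = vals,
                 extractor_name = sprintf("precomputed(%s)", basename(path))),
            class = "feature_matrix")
}

#' Save a feature matrix as a CSV keyed by cell id
#'
#' @param features a `feature_matrix` or matrix.
#' @param path CSV path.
#' @param cell_ids per-cell identifiers.
#' @return `path`, invisibly.
#' @export
save_features <- function(features, path, cell_ids) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (nrow(X) != length(cell_ids)) {
    stopf("%d feature rows for %d cell ids", nrow(X), length(cell_ids))
  }
  write_matrix_csv(X, path, row_ids = cell_ids,
                   col_ids = paste0("f", seq_len(ncol(X))))
  invisible(path)
}
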