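#' Spatial single-cell dataset container
#'
#' Bundles a cells-by-genes expression matrix with per-cell pixel coordinates
#' and optional annotation labels and field-of-view (FOV) identifiers. The
#' coordinate frame is that of the co-registered histology image: `coords[, 1]`
#' is x (column) and `coords[, 2]` is y (row), both 0-based pixels. Auxiliary
#' matrices of identical shape (e.g. a normalized or a denoised version of the
#' expression) live in named `layers`; the untouched input is kept in layer
#' `"raw"`.
#'
#' @param expression numeric cells x genes matrix, non-negative.
#' @param coords numeric cells x 2 matrix of (x, y) pixel coordinates.
#' @param gene_names character vector, one per gene; defaults to column names.
#' @param cell_ids character vector, one per cell; defaults to row names.
#' @param labels optional character vector of per-cell category labels.
#' @param fov optional integer vector of per-cell field-of-view IDs.
#' @param layers named list of cells x genes matrices.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expression, coords, gene_names = NULL,
                            cell_ids = NULL, labels = NULL, fov = NULL,
                            layers = list()) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  g <- ncol(expression)
  if (is.null(gene_names)) {
    gene_names <- colnames(expression)
    if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(g))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(expression)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  layers <- lapply(layers, function(l) {
    l <- as.matrix(l)
    storage.mode(l) <- "double"
    l
  })
  ds <- structure(
    list(expression = expression, coords = coords,
         gene_names = as.character(gene_names),
         cell_ids = as.character(cell_ids),
         labels = if (is.null(labels)) NULL else as.character(labels),
         fov = if (is.null(fov)) NULL else as.integer(fov),
         layers = layers),
    class = "spatial_dataset")
  validate_spatial_dataset(ds)
  ds
}

validate_spatial_dataset <- function(ds) {
  n <- nrow(ds$expression)
  g <- ncol(ds$expression)
  if (any(ds$expression < 0)) {
    stopf("expression matrix has negative entries")
  }
  if (!all(is.finite(ds$coords))) {
    stopf("coords must be finite (non-finite value at cell row %d)",
          which(!apply(is.finite(ds$coords), 1L, all))[1L])
  }
  if (nrow(ds$coords) != n || ncol(ds$coords) != 2L) {
    stopf("cell axis mismatch: coords has %d rows for %d cells",
          nrow(ds$coords), n)
  }
  if (length(ds$gene_names) != g) {
    stopf("gene axis mismatch: %d gene names for %d genes",
          length(ds$gene_names), g)
  }
  if (length(ds$cell_ids) != n) {
    stopf("cell axis mismatch: %d cell ids for %d cells",
          length(ds$cell_ids), n)
  }
  if (!is.null(ds$labels) && length(ds$labels) != n) {
    stopf("cell axis mismatch: %d labels for %d cells", length(ds$labels), n)
  }
  if (!is.null(ds$fov) && length(ds$fov) != n) {
    stopf("cell axis mismatch: %d fov ids for %d cells", length(ds$fov), n)
  }
  for (nm in names(ds$layers)) {
    l <- ds$layers[[nm]]
    if (!identical(dim(l), dim(ds$expression))) {
      stopf("layer '%s' shape (%d, %d) differs from expression (%d, %d)",
            nm, nrow(l), ncol(l), n, g)
    }
  }
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  layers: %s\n",
              if (length(x$layers)) paste(names(x$layers), collapse = ", ")
              else "(none)"))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d classes\n", length(unique(x$labels))))
  }
  if (!is.null(x$fov)) cat(sprintf("  fovs: %d\n", length(unique(x$fov))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expression)

#' Get or set a named layer of a spatial dataset
#'
#' @param ds a `spatial_dataset`.
#' @param name layer name, e.g. `"raw"`, `"norm"`, `"enhanced"`.
#' @param value cells x genes matrix to store.
#' @return `get_layer` returns the matrix; `set_layer` the updated dataset.
#' @export
get_layer <- function(ds, name) {
  if (!name %in% names(ds$layers)) {
    stopf("dataset has no layer '%s' (available: %s)", name,
          paste(names(ds$layers), collapse = ", "))
  }
  ds$layers[[name]]
}

#' @rdname get_layer
#' @export
set_layer <- function(ds, name, value) {
  value <- as.matrix(value)
  if (!identical(dim(value), dim(ds$expression))) {
    stopf("layer '%s' shape (%d, %d) differs from expression (%d, %d)",
          name, nrow(value), ncol(value),
          nrow(ds$expression), ncol(ds$expression))
  }
  ds$layers[[name]] <- value
  ds
}

#' Load a spatial dataset from expression, coordinate and annotation files
#'
#' Expression can be a dense CSV (cells in rows, header row of gene names,
#' first column of cell ids) or a MatrixMarket triplet with sidecar gene and
#' cell name files (one name per line). The coordinate CSV must have columns
#' `x` and `y` (pixels), one row per cell, and may carry a `cell_id` column.
#'
#' @param expr_path path to the expression matrix.
#' @param coords_path path to the coordinates CSV.
#' @param format `"csv"` or `"mtx"`.
#' @param genes_path,cells_path sidecar name files (required for `"mtx"`).
#' @param labels_path optional CSV with a `label` column.
#' @param fov_path optional CSV with a `fov` column.
#' @param transpose set `TRUE` when the matrix is stored genes x cells
#'   (the 10x convention).
#' @return A `spatial_dataset` with the untouched input in layer `"raw"`.
#' @export
load_dataset <- function(expr_path, coords_path, format = c("csv", "mtx"),
                         genes_path = NULL, cells_path = NULL,
                         labels_path = NULL, fov_path = NULL,
                         transpose = FALSE) {
  format <- match.arg(format)
  for (p in c(expr_path, coords_path, genes_path, cells_path, labels_path,
              fov_path)) {
    if (!is.null(p) && !file.exists(p)) stopf("file not found: %s", p)
  }
  if (format == "csv") {
    x <- read_matrix_csv(expr_path, has_row_ids = TRUE)
    gene_names <- colnames(x)
    cell_ids <- rownames(x)
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      stopf("mtx format needs genes_path and cells_path sidecar files")
    }
    x <- as.matrix(Matrix::readMM(expr_path))
    gene_names <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
  }
  if (transpose) x <- t(x)
  if (length(gene_names) != ncol(x)) {
    stopf("gene axis mismatch: %d names in sidecar for %d matrix columns",
          length(gene_names), ncol(x))
  }
  if (length(cell_ids) != nrow(x)) {
    stopf("cell axis mismatch: %d ids in sidecar for %d matrix rows",
          length(cell_ids), nrow(x))
  }
  cdf <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(cdf))) {
    stopf("coordinate file must have 'x' and 'y' columns")
  }
  if (nrow(cdf) != nrow(x)) {
    stopf("cell axis mismatch: coordinate file has %d rows for %d cells",
          nrow(cdf), nrow(x))
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(cdf[[col]]))
    bad <- which(is.na(v) & !is.na(cdf[[col]]))
    if (length(bad)) {
      stopf("non-numeric coordinate '%s' in column %s at row %d",
            cdf[[col]][bad[1L]], col, bad[1L])
    }
    cdf[[col]] <- v
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    ldf <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!"label" %in% names(ldf)) stopf("label file must have a 'label' column")
    if (nrow(ldf) != nrow(x)) {
      stopf("cell axis mismatch: label file has %d rows for %d cells",
            nrow(ldf), nrow(x))
    }
    labels <- as.character(ldf$label)
  }
  fov <- NULL
  if (!is.null(fov_path)) {
    fdf <- utils::read.csv(fov_path, stringsAsFactors = FALSE)
    if (!"fov" %in% names(fdf)) stopf("fov file must have a 'fov' column")
    if (nrow(fdf) != nrow(x)) {
      stopf("cell axis mismatch: fov file has %d rows for %d cells",
            nrow(fdf), nrow(x))
    }
    fov <- as.integer(fdf$fov)
  }
  rownames(x) <- NULL
  colnames(x) <- NULL
  spatial_dataset(x, as.matrix(cdf[, c("x", "y")]), gene_names = gene_names,
                  cell_ids = cell_ids, labels = labels, fov = fov,
                  layers = list(raw = x))
}

#' Persist a spatial dataset to a directory archive
#'
#' Writes all layers, names, coordinates and annotations as plain-text files
#' (full-precision CSV plus a small JSON manifest) so that
#' `read_spatial_dataset(save_dataset(ds, dir))` reproduces `ds` exactly for
#' integer counts and to representation precision for floats.
#'
#' @param ds a `spatial_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path) {
  validate_spatial_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create archive directory: %s", path)
  wr <- function(x, f) {
    ok <- tryCatch({ write_matrix_csv(x, file.path(path, f),
                                      row_ids = ds$cell_ids,
                                      col_ids = ds$gene_names); TRUE },
                   error = function(e) FALSE)
    if (!ok) stopf("I/O failure writing %s", file.path(path, f))
  }
  wr(ds$expression, "expression.csv")
  for (nm in names(ds$layers)) wr(ds$layers[[nm]], paste0("layer_", nm, ".csv"))
  write_matrix_csv(ds$coords, file.path(path, "coords.csv"),
                   row_ids = ds$cell_ids, col_ids = c("x", "y"))
  writeLines(ds$gene_names, file.path(path, "genes.txt"))
  writeLines(ds$cell_ids, file.path(path, "cells.txt"))
  if (!is.null(ds$labels)) {
    utils::write.csv(data.frame(cell_id = ds$cell_ids, label = ds$labels),
                     file.path(path, "labels.csv"), row.names = FALSE)
  }
  if (!is.null(ds$fov)) {
    utils::write.csv(data.frame(cell_id = ds$cell_ids, fov = ds$fov),
                     file.path(path, "fov.csv"), row.names = FALSE)
  }
  meta <- list(format = "stfuse-archive", version = 1L,
               n_cells = nrow(ds$expression), n_genes = ncol(ds$expression),
               layers = as.list(names(ds$layers)),
               has_labels = !is.null(ds$labels), has_fov = !is.null(ds$fov))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
read_spatial_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("not a dataset archive (no meta.json): %s", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  x <- read_matrix_csv(file.path(path, "expression.csv"), has_row_ids = TRUE)
  gene_names <- readLines(file.path(path, "genes.txt"))
  cell_ids <- readLines(file.path(path, "cells.txt"))
  coords <- read_matrix_csv(file.path(path, "coords.csv"), has_row_ids = TRUE)
  layers <- list()
  for (nm in meta$layers) {
    layers[[nm]] <- unname(read_matrix_csv(
      file.path(path, paste0("layer_", nm, ".csv")), has_row_ids = TRUE))
  }
  labels <- NULL
  if (isTRUE(meta$has_labels)) {
    labels <- utils::read.csv(file.path(path, "labels.csv"),
                              stringsAsFactors = FALSE)$label
    labels <- as.character(labels)
  }
  fov <- NULL
  if (isTRUE(meta$has_fov)) {
    fov <- utils::read.csv(file.path(path, "fov.csv"))$fov
  }
  rownames(x) <- NULL
  colnames(x) <- NULL
  spatial_dataset(x, unname(coords), gene_names = gene_names,
                  cell_ids = cell_ids, labels = labels, fov = fov,
                  layers = layers)
}
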