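# internal helpers shared across modules

# round half away from zero (locale/IEC-independent, unlike base round)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# full-precision dense matrix CSV (round-trips doubles exactly via %.17g)
write_matrix_csv <- function(x, path, row_ids = NULL, col_ids = NULL) {
  x <- as.matrix(x)
  header <- if (is.null(col_ids)) paste0("V", seq_len(ncol(x))) else col_ids
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(row_ids)) {
    header <- c("cell_id", header)
    lines <- paste(row_ids, lines, sep = ",")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(lines, con)
  invisible(path)
}

read_matrix_csv <- function(path, has_row_ids = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  row_ids <- NULL
  if (has_row_ids) {
    row_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  if (!is.null(row_ids)) rownames(x) <- row_ids
  x
}

# map a function over parallel nested lists whose leaves are numeric arrays
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- vector("list", length(trees[[1L]]))
    names(out) <- names(trees[[1L]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# reduce over all numeric leaves of a nested list
tree_reduce <- function(f, tree, init = 0) {
  acc <- init
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk) else acc <<- f(acc, node)
    invisible(NULL)
  }
  walk(tree)
  acc
}

tree_global_norm <- function(tree) {
  sqrt(tree_reduce(function(acc, leaf) acc + sum(leaf^2), tree))
}
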