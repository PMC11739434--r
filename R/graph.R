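#' Build the cellular spatial neighbor graph from a Euclidean radius
#'
#' Two cells are neighbors iff their Euclidean pixel distance is at most
#' `radius` (closed ball). Self-pairs are excluded; the attention layers of
#' the fusion model re-introduce the self term explicitly. Uses grid-bucket
#' spatial hashing, so 1e5 cells are practical.
#'
#' @param coords cells x 2 matrix of finite (x, y) pixel coordinates.
#' @param radius neighbor threshold in pixels, >= 0.
#' @param fov optional per-cell field-of-view IDs; when given, edges that
#'   would cross FOV boundaries are dropped (by default cells are linked
#'   regardless of FOV).
#' @return An object of class `spatial_graph`: `n_cells`, `edges` (two-column
#'   matrix of 1-based index pairs with i < j), `radius`, `degrees`.
#' @export
build_radius_graph <- function(coords, radius, fov = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stopf("coords must have two columns")
  if (!all(is.finite(coords))) {
    stopf("coords must be finite (non-finite at row %d)",
          which(!apply(is.finite(coords), 1L, all))[1L])
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stopf("radius must be a single number >= 0")
  }
  n <- nrow(coords)
  edges <- if (radius == 0) {
    # only exactly coincident points are neighbors
    key <- paste(coords[, 1L], coords[, 2L], sep = "\r")
    grp <- split(seq_len(n), key)
    do.call(rbind, lapply(grp[lengths(grp) > 1L], function(ii) {
      t(utils::combn(ii, 2L))
    }))
  } else {
    h <- radius
    bx <- floor(coords[, 1L] / h)
    by <- floor(coords[, 2L] / h)
    bin_of <- paste(bx, by, sep = "\r")
    bins <- split(seq_len(n), bin_of)
    bin_xy <- do.call(rbind, lapply(strsplit(names(bins), "\r", fixed = TRUE),
                                    as.numeric))
    lookup <- new.env(parent = emptyenv(), size = length(bins))
    for (b in seq_along(bins)) assign(names(bins)[b], b, envir = lookup)
    r2 <- radius^2
    acc <- vector("list", length(bins))
    # half-stencil over neighboring bins so each unordered pair is seen once
    stencil <- rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
    for (b in seq_along(bins)) {
      ii <- bins[[b]]
      found <- list()
      for (s in seq_len(nrow(stencil))) {
        key <- paste(bin_xy[b, 1L] + stencil[s, 1L],
                     bin_xy[b, 2L] + stencil[s, 2L], sep = "\r")
        ob <- if (exists(key, envir = lookup, inherits = FALSE)) {
          get(key, envir = lookup)
        } else next
        jj <- bins[[ob]]
        d2 <- outer(coords[ii, 1L], coords[jj, 1L], "-")^2 +
              outer(coords[ii, 2L], coords[jj, 2L], "-")^2
        hit <- which(d2 <= r2, arr.ind = TRUE)
        if (nrow(hit)) {
          a <- ii[hit[, 1L]]
          bb <- jj[hit[, 2L]]
          keep <- if (s == 1L) a < bb else rep(TRUE, length(a))
          if (any(keep)) {
            found[[length(found) + 1L]] <-
              cbind(pmin(a[keep], bb[keep]), pmax(a[keep], bb[keep]))
          }
        }
      }
      if (length(found)) acc[[b]] <- do.call(rbind, found)
    }
    do.call(rbind, acc)
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  }
  if (!is.null(fov) && nrow(edges)) {
    if (length(fov) != n) stopf("%d fov ids for %d cells", length(fov), n)
    edges <- edges[fov[edges[, 1L]] == fov[edges[, 2L]], , drop = FALSE]
  }
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  deg <- tabulate(edges[, 1L], n) + tabulate(edges[, 2L], n)
  structure(list(n_cells = n, edges = edges, radius = radius, degrees = deg),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  s <- neighbor_stats(x)
  cat(sprintf("spatial_graph: %d cells, %d edges (radius %g px)\n",
              x$n_cells, nrow(x$edges), x$radius))
  cat(sprintf("  mean degree %.2f, %d isolated\n", s$mean_degree, s$isolated))
  invisible(x)
}

#' Neighbor-count summary for radius tuning
#'
#' The per-tissue radius is chosen to give comparable average neighbor counts
#' across datasets; this reports the quantities used for that tuning.
#'
#' @param graph a `spatial_graph`.
#' @return list with `mean_degree` and `isolated` (count of degree-0 cells).
#' @export
neighbor_stats <- function(graph) {
  list(mean_degree = if (graph$n_cells > 0) mean(graph$degrees) else 0,
       isolated = sum(graph$degrees == 0L))
}

#' Per-tissue default neighbor radii
#'
#' Presets matching the radii used on the reference datasets: 80 px for lung
#' (CosMx NSCLC), 300 px for breast (Visium), 20 px for colorectal (Visium).
#'
#' @param tissue one of `"lung"`, `"breast"`, `"colorectal"`.
#' @return radius in pixels.
#' @export
tissue_radius <- function(tissue = c("lung", "breast", "colorectal")) {
  tissue <- match.arg(tissue)
  c(lung = 80, breast = 300, colorectal = 20)[[tissue]]
}

#' Write / read a graph edge list as a two-column CSV of cell indices
#'
#' @param graph a `spatial_graph`.
#' @param path CSV path.
#' @param n_cells number of cells (needed on read).
#' @param radius radius recorded on read.
#' @return `read_graph_csv` returns a `spatial_graph`.
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(data.frame(i = graph$edges[, 1L], j = graph$edges[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
read_graph_csv <- function(path, n_cells, radius = NA_real_) {
  df <- utils::read.csv(path)
  edges <- cbind(pmin(df$i, df$j), pmax(df$i, df$j))
  edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  if (nrow(edges) && max(edges) > n_cells) {
    stopf("edge index %d exceeds n_cells = %d", max(edges), n_cells)
  }
  deg <- tabulate(edges[, 1L], n_cells) + tabulate(edges[, 2L], n_cells)
  structure(list(n_cells = as.integer(n_cells), edges = edges,
                 radius = radius, degrees = deg),
            class = "spatial_graph")
}

# directed edge index (both directions + self loops) with padded per-node
# slots, precomputed once per graph for the attention layers
attention_index <- function(graph) {
  n <- graph$n_cells
  e <- graph$edges
  src <- c(seq_len(n), e[, 1L], e[, 2L])
  dst <- c(seq_len(n), e[, 2L], e[, 1L])
  o <- order(src, dst)
  src <- src[o]
  dst <- dst[o]
  counts <- tabulate(src, n)
  m <- length(src)
  # segment-sum bookkeeping: edges are sorted by src, so per-source sums are
  # cumsum differences at group ends; for per-destination sums we store a
  # permutation that sorts by dst (every node has a self loop, so no group
  # is empty)
  ends_src <- cumsum(counts)
  ord_dst <- order(dst, src)
  ends_dst <- cumsum(tabulate(dst, n))
  list(n = n, m = m, src = src, dst = dst,
       ends_src = ends_src, ord_dst = ord_dst, ends_dst = ends_dst)
}

# column-wise segment sums of an m x d matrix (or length-m vector) over
# contiguous groups ending at `ends`, via one cumulative sum; only the very
# first group of the first column starts at running-sum zero, so a single
# shifted subtraction does the rest
segment_sum <- function(x, ends) {
  n <- length(ends)
  if (is.matrix(x)) {
    m <- nrow(x)
    d <- ncol(x)
    cs <- cumsum(x)                             # column-major running sum
    off <- rep((seq_len(d) - 1L) * m, each = n)
    hi <- rep(ends, d) + off
    lo <- rep(c(0L, ends[-n]), d) + off
    v <- cs[hi]
    v[-1L] <- v[-1L] - cs[lo[-1L]]
    matrix(v, n, d)
  } else {
    cs <- cumsum(x)
    v <- cs[ends]
    v[-1L] <- v[-1L] - cs[ends[-n]]
    v
  }
}
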