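#' Synthetic tissue benchmark configuration
#'
#' Fixes the study conditions of the built-in benchmark: K spatial domains
#' laid out over a square tissue, domain-specific marker genes, negative
#' binomial counts with heavy independent dropout, and a histology texture
#' whose domain signal is controlled by `texture_contrast`. Defaults emulate
#' an annotated targeted-panel dataset at desk scale: 800 cells, 200 genes,
#' 4 domains, 10 markers per domain at log2 fold change 2, baseline mean 0.5
#' counts/gene, overdispersion 0.5, 60% dropout.
#'
#' @param n_cells,n_genes,k_domains problem size (k >= 2).
#' @param layout `"stripes"` (equal vertical bands), `"blobs"` (labels drawn
#'   from equal-weight Gaussians at k random centers) or `"voronoi"` (nearest
#'   of k random sites).
#' @param markers_per_domain markers planted per domain (disjoint across
#'   domains).
#' @param marker_lfc log2 fold change of a marker inside its domain.
#' @param base_mean baseline mean count per gene per cell.
#' @param dropout_rate probability an observed entry is zeroed.
#' @param dispersion negative-binomial overdispersion alpha (variance =
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param image_side histology image side in pixels.
#' @param texture_contrast per-domain visual separation in \[0, 1\]; 0 makes
#'   the image carry no domain signal.
#' @param seed integer seed; every generator draws from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 800L, n_genes = 200L, k_domains = 4L,
                             layout = c("stripes", "blobs", "voronoi"),
                             markers_per_domain = 10L, marker_lfc = 2,
                             base_mean = 0.5, dropout_rate = 0.6,
                             dispersion = 0.5, image_side = 480L,
                             texture_contrast = 0.8, seed = 1L) {
  layout <- match.arg(layout)
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              k_domains = as.integer(k_domains), layout = layout,
              markers_per_domain = as.integer(markers_per_domain),
              marker_lfc = marker_lfc, base_mean = base_mean,
              dropout_rate = dropout_rate, dispersion = dispersion,
              image_side = as.integer(image_side),
              texture_contrast = texture_contrast, seed = as.integer(seed))
  if (cfg$k_domains < 2L) stopf("k_domains must be >= 2")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    stopf("dropout_rate must be in [0, 1]")
  }
  if (cfg$texture_contrast < 0 || cfg$texture_contrast > 1) {
    stopf("texture_contrast must be in [0, 1]")
  }
  if (cfg$n_cells < 1L || cfg$n_genes < 1L || cfg$markers_per_domain < 1L ||
      cfg$image_side < 1L) {
    stopf("all counts must be >= 1")
  }
  if (cfg$markers_per_domain * cfg$k_domains > cfg$n_genes) {
    stopf("markers (%d x %d) exceed n_genes (%d)",
          cfg$markers_per_domain, cfg$k_domains, cfg$n_genes)
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate the domain geography
#'
#' Cell coordinates are uniform over the image square; labels follow the
#' configured layout. For stripes the per-domain cell counts are equalized
#' (cells allocated evenly to bands, uniform within each band — the marginal
#' distribution stays uniform on the square), so that nucleus density in the
#' rendered image cannot encode stripe identity and the image carries no
#' domain signal at zero texture contrast. Sites/centers of the other
#' layouts are resampled until every domain is non-empty.
#'
#' @param config a `synthetic_config`.
#' @return list with `coords` (n x 2), `labels` (integers in `[0, k)`) and
#'   `geometry` (the sites/centers needed to render the matching histology).
#' @export
simulate_domains <- function(config) {
  set_global_seed(config$seed)
  n <- config$n_cells
  k <- config$k_domains
  side <- config$image_side
  if (config$layout == "stripes") {
    band <- side / k
    counts <- rep(n %/% k, k)
    if (n %% k) counts[seq_len(n %% k)] <- counts[seq_len(n %% k)] + 1L
    labels <- rep(seq_len(k) - 1L, times = counts)
    coords <- cbind(x = (labels + stats::runif(n)) * band,
                    y = stats::runif(n, 0, side))
    return(list(coords = coords, labels = as.integer(labels),
                geometry = NULL))
  }
  coords <- cbind(x = stats::runif(n, 0, side), y = stats::runif(n, 0, side))
  assign_labels <- function() {
    if (config$layout == "voronoi") {
      sites <- cbind(stats::runif(k, 0, side), stats::runif(k, 0, side))
      d2 <- outer(coords[, 1L], sites[, 1L], "-")^2 +
            outer(coords[, 2L], sites[, 2L], "-")^2
      list(labels = max.col(-d2) - 1L, geometry = sites)
    } else {
      centers <- cbind(stats::runif(k, 0.15 * side, 0.85 * side),
                       stats::runif(k, 0.15 * side, 0.85 * side))
      sigma <- side / k
      d2 <- outer(coords[, 1L], centers[, 1L], "-")^2 +
            outer(coords[, 2L], centers[, 2L], "-")^2
      w <- exp(-d2 / (2 * sigma^2))
      labels <- integer(n)
      for (i in seq_len(n)) {
        labels[i] <- sample.int(k, 1L, prob = w[i, ]) - 1L
      }
      list(labels = labels, geometry = centers)
    }
  }
  res <- assign_labels()
  tries <- 0L
  while (length(unique(res$labels)) < k && tries < 100L) {
    res <- assign_labels()
    tries <- tries + 1L
  }
  if (length(unique(res$labels)) < k) {
    stopf("could not populate all %d domains with %d cells", k, n)
  }
  list(coords = coords, labels = as.integer(res$labels),
       geometry = res$geometry)
}

#' Simulate expression with markers, overdispersion and dropout
#'
#' Clean means are `mu_ig = base_mean * 2^(marker_lfc * [g is a marker of
#' domain(i)])`; observed counts are negative binomial (Poisson when
#' `dispersion = 0`) with independent Bernoulli dropout zeroing recorded in
#' the mask. Markers are the first `k * markers_per_domain` genes, assigned
#' blockwise and disjoint across domains.
#'
#' @param labels per-cell domain labels in `[0, k)`.
#' @param config a `synthetic_config`.
#' @return list with `observed` (counts after dropout) and `truth`
#'   (`domain_labels`, `clean_expression` = the mean matrix, `dropout_mask`,
#'   `marker_assignment`).
#' @export
simulate_expression <- function(labels, config) {
  set_global_seed(config$seed + 1000L)
  n <- length(labels)
  g <- config$n_genes
  k <- config$k_domains
  mpd <- config$markers_per_domain
  marker_domain <- rep(NA_integer_, g)
  marker_domain[seq_len(k * mpd)] <- rep(seq_len(k) - 1L, each = mpd)
  mu <- matrix(config$base_mean, n, g)
  for (d in seq_len(k) - 1L) {
    genes <- which(marker_domain == d)
    cells <- which(labels == d)
    if (length(cells)) {
      mu[cells, genes] <- config$base_mean * 2^config$marker_lfc
    }
  }
  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(n * g, mu = mu, size = 1 / config$dispersion), n, g)
  } else {
    matrix(stats::rpois(n * g, lambda = mu), n, g)
  }
  mask <- matrix(stats::runif(n * g) < config$dropout_rate, n, g)
  observed <- counts * !mask
  truth <- list(domain_labels = as.integer(labels), clean_expression = mu,
                dropout_mask = mask,
                marker_assignment = data.frame(
                  gene = seq_len(g)[!is.na(marker_domain)],
                  domain = marker_domain[!is.na(marker_domain)]))
  list(observed = observed, truth = truth)
}

# pixel-level domain map following the same layout rule as the cells
domain_pixel_map <- function(config, geometry) {
  side <- config$image_side
  k <- config$k_domains
  xs <- seq_len(side) - 1L   # 0-based pixel columns/rows
  if (config$layout == "stripes") {
    band <- side / k
    col_dom <- pmin(floor(xs / band), k - 1L)
    matrix(rep(col_dom, each = side), side, side)   # rows y, cols x
  } else {
    d2 <- array(0, c(side, side, k))
    for (d in seq_len(k)) {
      dx2 <- (xs - geometry[d, 1L])^2
      dy2 <- (xs - geometry[d, 2L])^2
      d2[, , d] <- outer(dy2, dx2, "+")
    }
    apply(d2, c(1L, 2L), which.min) - 1L
  }
}

#' Render a histology image matched to the domain layout
#'
#' Each domain gets a base color and a procedural texture (a seeded smooth
#' noise field with domain-specific spatial frequency), both scaled by
#' `texture_contrast`; dark ellipses mark cell positions. At contrast 0 all
#' domains are rendered identically, so the image carries no domain signal;
#' expression noise and image appearance are conditionally independent given
#' the labels.
#'
#' @param coords cell coordinates from [simulate_domains()].
#' @param labels per-cell domain labels.
#' @param config a `synthetic_config`.
#' @param geometry layout geometry from [simulate_domains()].
#' @return A `histology_image`.
#' @export
render_histology <- function(coords, labels, config, geometry = NULL) {
  set_global_seed(config$seed + 2000L)
  side <- config$image_side
  k <- config$k_domains
  ctr <- config$texture_contrast
  dom <- domain_pixel_map(config, geometry)
  # distinct base colors per domain, centered on mid-gray, scaled by contrast
  hue <- 2 * pi * (seq_len(k) - 1L) / k
  base <- cbind(128 + 80 * ctr * cos(hue),
                128 + 80 * ctr * sin(hue),
                128 + 80 * ctr * cos(hue + pi / 3))
  img <- array(0, c(side, side, 3L))
  yy <- matrix(seq_len(side) - 1L, side, side)
  xx <- t(yy)
  for (d in seq_len(k)) {
    m <- dom == (d - 1L)
    freq <- 2 * pi * (2 + 3 * (d - 1L)) / side
    phase <- stats::runif(2L, 0, 2 * pi)
    tex <- 40 * ctr * sin(freq * xx + phase[1L]) * sin(freq * yy + phase[2L])
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- base[d, ch] + tex[m]
      img[, , ch] <- plane
    }
  }
  # domain-independent speckle so a flat image still looks like tissue
  img <- img + array(stats::rnorm(side * side * 3L, 0, 4), c(side, side, 3L))
  # dark nuclei at cell positions (identical for every domain)
  cx <- as.integer(round_half_away(coords[, 1L]))
  cy <- as.integer(round_half_away(coords[, 2L]))
  r <- 2L
  for (i in seq_along(cx)) {
    rows <- max(0L, cy[i] - r):min(side - 1L, cy[i] + r)
    cols <- max(0L, cx[i] - r):min(side - 1L, cx[i] + r)
    inside <- outer((rows - cy[i])^2, (cols - cx[i])^2, "+") <= r^2
    for (ch in 1:3) {
      blk <- img[rows + 1L, cols + 1L, ch]
      blk[inside] <- blk[inside] * 0.35
      img[rows + 1L, cols + 1L, ch] <- blk
    }
  }
  histology_image(pmin(pmax(round_half_away(img), 0), 255))
}

#' Generate a complete synthetic benchmark
#'
#' Composes the three simulators into a ready-to-run benchmark: a
#' `spatial_dataset` (observed counts in layer `"raw"`, true domains as
#' labels), the matched `histology_image`, and the `SyntheticTruth` needed to
#' score denoising and domain recovery.
#'
#' @param config a `synthetic_config`.
#' @return list with `dataset`, `image`, `truth`, `config`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  dom <- simulate_domains(config)
  expr <- simulate_expression(dom$labels, config)
  image <- render_histology(dom$coords, dom$labels, config, dom$geometry)
  ds <- spatial_dataset(expr$observed, dom$coords,
                        gene_names = paste0("gene", seq_len(config$n_genes)),
                        cell_ids = paste0("cell", seq_len(config$n_cells)),
                        labels = as.character(dom$labels),
                        layers = list(raw = expr$observed))
  list(dataset = ds, image = image, truth = expr$truth, config = config)
}
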