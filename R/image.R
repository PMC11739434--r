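#' Histology image container
#'
#' A co-registered RGB raster in the same pixel frame as the dataset
#' coordinates: `pixels[r + 1, c + 1, ch]` is the value at 0-based row `r`
#' (y) and column `c` (x), integers in \[0, 255\].
#'
#' @param pixels H x W x 3 array, values 0-255.
#' @param pixel_size optional microns-per-pixel scalar.
#' @return An object of class `histology_image`.
#' @export
histology_image <- function(pixels, pixel_size = NULL) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stopf("pixels must be an H x W x 3 RGB array")
  }
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L) {
    stopf("image must have positive height and width")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stopf("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("histology_image: %d x %d px, RGB\n", d[1L], d[2L]))
  invisible(x)
}

#' Read / write an RGB histology image (PNG or TIFF)
#'
#' Grayscale rasters are replicated to three channels and an alpha channel is
#' dropped; values are rescaled to integer \[0, 255\].
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param image a `histology_image` (for writing).
#' @return `read_image` returns a `histology_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (use png or tiff)", ext))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3L] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3L] == 4L) raw <- raw[, , 1:3, drop = FALSE]
  histology_image(round_half_away(raw * 255))
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  x <- image$pixels / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stopf("unsupported image format '.%s' (use png or tiff)", ext))
  invisible(path)
}

#' Extract one cell-centered patch per cell
#'
#' Patch `i` covers the half-open pixel window
#' `[x_i - size/2, x_i + size/2) x [y_i - size/2, y_i + size/2)` of the image;
#' pixels falling outside the image are zero-filled (black). Non-integer
#' coordinates are rounded half-away-from-zero to pixel centers first.
#'
#' @param image a `histology_image`.
#' @param dataset a `spatial_dataset` whose coords share the image frame.
#' @param size even patch side in pixels (default 240).
#' @return A `patch_set`: list with `patches`, a cells x 3 x size x size
#'   array aligned to the dataset cell axis, and `size`.
#' @export
crop_patches <- function(image, dataset, size = 240L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L) stopf("patch size must be even and >= 2")
  px <- image$pixels
  H <- dim(px)[1L]
  W <- dim(px)[2L]
  n <- nrow(dataset$coords)
  half <- size %/% 2L
  xs <- as.integer(round_half_away(dataset$coords[, 1L]))
  ys <- as.integer(round_half_away(dataset$coords[, 2L]))
  patches <- array(0, dim = c(n, 3L, size, size))
  for (i in seq_len(n)) {
    rows <- (ys[i] - half) + 0:(size - 1L)   # 0-based image rows
    cols <- (xs[i] - half) + 0:(size - 1L)
    rok <- which(rows >= 0L & rows < H)
    cok <- which(cols >= 0L & cols < W)
    if (length(rok) == 0L || length(cok) == 0L) {
      warnf("cell %d at (%d, %d) lies entirely outside the image; patch is all padding",
            i, xs[i], ys[i])
      next
    }
    sub <- px[rows[rok] + 1L, cols[cok] + 1L, , drop = FALSE]
    patches[i, , rok, cok] <- aperm(sub, c(3L, 1L, 2L))
  }
  structure(list(patches = patches, size = size), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of 3 x %d x %d\n",
              dim(x$patches)[1L], x$size, x$size))
  invisible(x)
}
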