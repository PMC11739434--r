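test_that("dataset construction validates the cell axis and negativity", {
  X <- matrix(1:6, 3, 2)
  coords <- cbind(c(0, 1, 2), c(0, 1, 2))
  ds <- spatial_dataset(X, coords)
  expect_identical(dim(ds), c(3L, 2L))
  expect_error(spatial_dataset(X, coords[1:2, ]), "cell axis")
  expect_error(spatial_dataset(-X, coords), "negative")
  expect_error(spatial_dataset(X, coords, labels = c("a", "b")), "cell axis")
  expect_error(spatial_dataset(X, cbind(c(0, NA, 2), c(0, 1, 2))), "finite")
})

test_that("load_dataset reads csv and mtx triplets and flags mismatches", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 0, 2, 0, 3, 4), 3, 2)
  stfuse:::write_matrix_csv(X, file.path(dir, "expr.csv"),
                            row_ids = paste0("c", 1:3),
                            col_ids = c("g1", "g2"))
  write.csv(data.frame(x = c(1, 2, 3), y = c(4, 5, 6)),
            file.path(dir, "coords.csv"), row.names = FALSE)
  ds <- load_dataset(file.path(dir, "expr.csv"), file.path(dir, "coords.csv"),
                     format = "csv")
  expect_identical(dim(ds$expression), c(3L, 2L))
  expect_identical(ds$layers$raw, ds$expression)

  # mtx triplet with sidecars
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), file.path(dir, "m.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "genes.txt"))
  writeLines(paste0("c", 1:3), file.path(dir, "cells.txt"))
  ds2 <- load_dataset(file.path(dir, "m.mtx"), file.path(dir, "coords.csv"),
                      format = "mtx", genes_path = file.path(dir, "genes.txt"),
                      cells_path = file.path(dir, "cells.txt"))
  expect_equal(ds2$expression, X, ignore_attr = TRUE)

  # 4 coordinate rows against 3 cells names the cell axis
  write.csv(data.frame(x = 1:4, y = 1:4), file.path(dir, "coords4.csv"),
            row.names = FALSE)
  expect_error(load_dataset(file.path(dir, "expr.csv"),
                            file.path(dir, "coords4.csv"), format = "csv"),
               "cell axis")

  # non-numeric coordinate reports the row
  write.csv(data.frame(x = c("1", "oops", "3"), y = c(1, 2, 3)),
            file.path(dir, "coordsbad.csv"), row.names = FALSE)
  expect_error(load_dataset(file.path(dir, "expr.csv"),
                            file.path(dir, "coordsbad.csv"), format = "csv"),
               "row 2")
})

test_that("archive round-trip is the identity on content", {
  set.seed(11)
  X <- matrix(rpois(10 * 5, 4), 10, 5)
  enh <- matrix(runif(50), 10, 5)
  ds <- spatial_dataset(X, cbind(runif(10), runif(10)),
                        labels = sample(letters[1:3], 10, TRUE),
                        fov = sample(1:2, 10, TRUE),
                        layers = list(raw = X, enhanced = enh))
  dir <- withr::local_tempdir()
  save_dataset(ds, file.path(dir, "arch"))
  ds2 <- read_spatial_dataset(file.path(dir, "arch"))
  expect_identical(unname(ds2$expression), unname(ds$expression))
  expect_identical(sort(names(ds2$layers)), c("enhanced", "raw"))
  expect_identical(unname(ds2$layers$raw), unname(X) * 1)
  expect_equal(unname(ds2$layers$enhanced), unname(enh))
  expect_identical(ds2$labels, ds$labels)
  expect_identical(ds2$fov, ds$fov)
  expect_equal(unname(ds2$coords), unname(ds$coords))
})

test_that("integer counts survive a 1000-cell round trip bitwise", {
  set.seed(4)
  X <- matrix(rpois(1000 * 20, 2), 1000, 20)
  ds <- spatial_dataset(X, cbind(runif(1000, 0, 480), runif(1000, 0, 480)),
                        layers = list(raw = X))
  dir <- withr::local_tempdir()
  save_dataset(ds, file.path(dir, "big"))
  ds2 <- read_spatial_dataset(file.path(dir, "big"))
  expect_identical(unname(ds2$expression), unname(X) * 1)
})

test_that("saving to an unwritable location is an I/O error", {
  expect_error(save_dataset(random_dataset(), "/proc/definitely/not/here"))
})

test_that("patch cropping matches the per-pixel oracle and centers cells", {
  set.seed(21)
  H <- 32; W <- 40
  px <- array(sample(0:255, H * W * 3, TRUE), c(H, W, 3))
  img <- histology_image(px)
  n <- 50
  coords <- cbind(runif(n, -6, W + 6), runif(n, -6, H + 6))
  X <- matrix(1, n, 2)
  ds <- spatial_dataset(X, coords)
  ps <- suppressWarnings(crop_patches(img, ds, size = 8))
  xs <- sign(coords[, 1]) * floor(abs(coords[, 1]) + 0.5)
  ys <- sign(coords[, 2]) * floor(abs(coords[, 2]) + 0.5)
  for (i in seq_len(n)) {
    expect_identical(ps$patches[i, , , ], patch_oracle(px, xs[i], ys[i], 8))
  }
})

test_that("a centered cell reproduces the central crop exactly", {
  set.seed(3)
  px <- array(as.double(sample(0:255, 48 * 48 * 3, TRUE)), c(48, 48, 3))
  img <- histology_image(px)
  ds <- spatial_dataset(matrix(1, 1, 1), cbind(24, 24))
  ps <- crop_patches(img, ds, size = 24)
  # patch pixel (12, 12) (0-based) is the image pixel at the cell coordinate
  expect_identical(ps$patches[1, , 13, 13], px[25, 25, ])
  expect_identical(ps$patches[1, , , ],
                   aperm(px[13:36, 13:36, ], c(3, 1, 2)))
})

test_that("a corner cell is padded with zeros in the out-of-image quadrant", {
  px <- array(200, c(100, 100, 3))
  img <- histology_image(px)
  ds <- spatial_dataset(matrix(1, 1, 1), cbind(0, 0))
  ps <- crop_patches(img, ds, size = 40)
  expect_true(all(ps$patches[1, , 1:20, 1:20] == 0))
  expect_true(all(ps$patches[1, , 21:40, 21:40] == 200))
})

test_that("a cell entirely outside the image warns and yields all padding", {
  img <- histology_image(array(100, c(20, 20, 3)))
  ds <- spatial_dataset(matrix(1, 1, 1), cbind(500, 500))
  expect_warning(ps <- crop_patches(img, ds, size = 10), "outside")
  expect_true(all(ps$patches == 0))
})

test_that("patch extraction is translation-consistent away from borders", {
  set.seed(31)
  base <- array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3))
  big1 <- array(0, c(60, 60, 3)); big1[11:40, 11:40, ] <- base
  big2 <- array(0, c(60, 60, 3)); big2[16:45, 21:50, ] <- base
  ds1 <- spatial_dataset(matrix(1, 1, 1), cbind(25, 25))
  ds2 <- spatial_dataset(matrix(1, 1, 1), cbind(35, 30))  # +10 x, +5 y
  p1 <- crop_patches(histology_image(big1), ds1, 16)
  p2 <- crop_patches(histology_image(big2), ds2, 16)
  expect_identical(p1$patches, p2$patches)
})

test_that("image round-trip through png preserves pixels", {
  set.seed(5)
  px <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(histology_image(px), path)
  img2 <- read_image(path)
  expect_identical(img2$pixels, px * 1)
})
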