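test_that("minimum-size ROI selection rejects small masses and center-crops large ones", {
  img <- matrix(runif(200 * 200), 200, 200)

  # bounding square 2*20 = 40 < 64 -> rejected
  expect_null(extract_roi(img, c(100, 100), 20, label = -1,
                          policy = "min_size_crop", min_side = 64))

  roi <- extract_roi(img, c(100, 100), 70, label = 1,
                     policy = "min_size_crop", min_side = 64)
  expect_s3_class(roi, "labeled_roi")
  expect_equal(roi$side_px, 64)
  # interior crop: pixels come straight from the image around the centroid
  expect_equal(roi$pixels, img[100 - 32 + seq_len(64), 100 - 32 + seq_len(64)])
  expect_equal(roi$label, 1)
})

test_that("resample policy crops the 2r bounding square and resamples to the target", {
  img <- matrix(runif(300 * 300), 300, 300)
  roi <- extract_roi(img, c(150, 150), 40, policy = "resample", target_side = 128)
  expect_equal(roi$side_px, 128)
  # a constant image survives interpolation exactly
  flat <- matrix(0.42, 100, 100)
  roi2 <- extract_roi(flat, c(50, 50), 25, policy = "resample", target_side = 64)
  expect_true(all(abs(roi2$pixels - 0.42) < 1e-12))
})

test_that("border-overrunning crops are mirror-padded, out-of-bounds centroids error", {
  img <- matrix(seq(0, 1, length.out = 100 * 100), 100, 100)
  roi <- extract_roi(img, c(2, 2), 40, policy = "min_size_crop", min_side = 64)
  expect_equal(roi$side_px, 64)
  expect_true(all(roi$pixels >= 0 & roi$pixels <= 1))
  # mirrored region reuses in-image intensities only
  expect_true(all(roi$pixels %in% img))
  expect_error(extract_roi(img, c(150, 50), 40), "outside image bounds")
  expect_error(extract_roi(img, c(50, 50), -1), "radius")
})

test_that("decompose produces the expected grid and rejects non-divisible shapes", {
  roi <- labeled_roi(matrix(runif(64 * 64), 64, 64), label = -1)
  g <- decompose(roi, c(8, 8))
  expect_equal(ncol(g$blocks), 64)
  expect_equal(nrow(g$blocks), 64)
  expect_equal(g$grid_shape, c(8, 8))

  g1 <- decompose(roi, c(64, 64))   # degenerates to whole-ROI SRC
  expect_equal(ncol(g1$blocks), 1)
  expect_equal(as.vector(roi$pixels), g1$blocks[, 1])

  expect_error(decompose(roi, c(7, 7)), "not divisible")
})

test_that("block ordering is row-major over the grid, column-major within blocks", {
  px <- matrix(seq_len(16), 4, 4)          # column-major 1..16
  g <- decompose(px, c(2, 2))
  # first block = top-left 2x2, vectorized column-major
  expect_equal(g$blocks[, 1], c(px[1:2, 1], px[1:2, 2]))
  # second block (row-major grid order) = top-right
  expect_equal(g$blocks[, 2], c(px[1:2, 3], px[1:2, 4]))
  expect_equal(g$blocks[, 3], c(px[3:4, 1], px[3:4, 2]))
})

test_that("decompose/reassemble round-trips exactly over random divisible pairs", {
  set.seed(42)
  for (side in c(32, 64)) {
    for (b in c(4, 8, 16, 32)) {
      px <- matrix(runif(side * side), side, side)
      expect_identical(reassemble(decompose(px, c(b, b))), px)
    }
  }
  # non-square blocks round-trip too
  px <- matrix(runif(24 * 24), 24, 24)
  expect_identical(reassemble(decompose(px, c(4, 8))), px)
})

test_that("reassemble validates grid consistency", {
  g <- decompose(matrix(runif(16), 4, 4), c(2, 2))
  g$blocks <- g$blocks[, -1, drop = FALSE]
  expect_error(reassemble(g), "inconsistent")
})

test_that("block training matrices stack the right blocks with aligned labels", {
  set.seed(1)
  rois <- list(labeled_roi(matrix(runif(16), 4, 4), -1),
               labeled_roi(matrix(runif(16), 4, 4), 1))
  mats <- build_block_training_matrices(rois, c(2, 2))
  expect_length(mats, 4)
  expect_equal(dim(mats[[1]]$Y), c(4, 2))
  # column i of matrix k equals block k of ROI i, exhaustively
  grids <- lapply(rois, decompose, block_shape = c(2, 2))
  for (k in 1:4) {
    for (i in 1:2) {
      expect_identical(mats[[k]]$Y[, i], grids[[i]]$blocks[, k])
    }
    expect_equal(mats[[k]]$column_labels, c(-1, 1))
  }
})

test_that("training-matrix construction enforces its preconditions", {
  expect_error(build_block_training_matrices(list(), c(2, 2)), "empty")
  r1 <- labeled_roi(matrix(runif(16), 4, 4), -1)
  r2 <- labeled_roi(matrix(runif(64), 8, 8), 1)
  expect_error(build_block_training_matrices(list(r1, r2), c(2, 2)), "mixed")
  expect_error(build_block_training_matrices(list(r1, r1), c(2, 2)), "both classes")
  expect_silent(build_block_training_matrices(list(r1, r1), c(2, 2),
                                              require_both_classes = FALSE))
})

test_that("labeled_roi validates its invariants", {
  expect_error(labeled_roi(matrix(0, 2, 3), -1), "square")
  expect_error(labeled_roi(matrix(2, 2, 2), -1), "\\[0, 1\\]")
  expect_error(labeled_roi(matrix(0.5, 2, 2), 3), "label")
  expect_equal(labeled_roi(matrix(0.5, 2, 2), "malignant")$label, 1)
  expect_true(is.na(labeled_roi(matrix(0.5, 2, 2))$label))
})

test_that("PNG write/read and the annotation ingestion path round-trip", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(side_px = 32, n_benign = 2, n_malignant = 2, seed = 5)
  csv <- write_synthetic_dataset(cfg, dir)
  ann <- read_annotations(csv)
  expect_equal(nrow(ann), 4)
  expect_setequal(ann$label_num, c(-1, 1))

  rois <- load_roi_dataset(ann, image_dir = dir, policy = "resample",
                           target_side = 32)
  expect_length(rois, 4)
  expect_true(all(vapply(rois, function(r) r$side_px, numeric(1)) == 32))

  # PNG round trip is exact up to 8-bit quantization
  orig <- generate_dataset(cfg)[[1]]
  p <- file.path(dir, "rt.png")
  write_gray_png(orig$pixels, p)
  expect_lt(max(abs(read_gray_image(p) - orig$pixels)), 1 / 255)
})

test_that("PGM reader parses ascii and binary variants", {
  dir <- withr::local_tempdir()
  vals <- c(0, 128, 255, 64, 32, 200)   # row-major: rows (0,128,255), (64,32,200)
  p2 <- file.path(dir, "a.pgm")
  writeLines(c("P2", "# comment", "3 2", "255", paste(vals, collapse = " ")), p2)
  expect_equal(read_gray_image(p2), matrix(vals / 255, 2, 3, byrow = TRUE))

  p5 <- file.path(dir, "b.pgm")
  con <- file(p5, "wb")
  writeChar("P5\n3 2\n255\n", con, eos = NULL)
  writeBin(as.raw(vals), con)
  close(con)
  expect_equal(read_gray_image(p5), matrix(vals / 255, 2, 3, byrow = TRUE))
})
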