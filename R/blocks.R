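#' Labeled square ROI
#'
#' Container for a square grayscale region of interest with a binary class
#' label. Intensities are validated to lie in \[0, 1\]; the label encoding is
#' benign = -1, malignant = +1, so that sign-based ensemble decisions map
#' directly onto class labels and malignant is the positive class of
#' TPR/TNR/AUC.
#'
#' @param pixels Square numeric matrix with values in \[0, 1\].
#' @param label Class label: `-1` (benign) or `+1` (malignant), or the
#'   strings `"benign"`/`"malignant"`. `NA` is allowed for unlabeled test
#'   ROIs.
#' @param source_id Opaque identifier carried through reports.
#' @return An object of class `labeled_roi` with fields `pixels`, `side_px`,
#'   `label`, `source_id`.
#' @export
labeled_roi <- function(pixels, label = NA, source_id = "") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop("ROI must be square, got ", nrow(pixels), "x", ncol(pixels))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("ROI intensities must be finite and within [0, 1]")
  }
  label <- normalize_label(label)
  structure(
    list(pixels = pixels, side_px = nrow(pixels), label = label,
         source_id = as.character(source_id)),
    class = "labeled_roi"
  )
}

# Accepts -1/+1, "benign"/"malignant", or NA.
normalize_label <- function(label) {
  if (length(label) != 1L) stop("label must be a scalar")
  if (is.na(label)) return(NA_real_)
  if (is.character(label)) {
    label <- match.arg(tolower(label), c("benign", "malignant"))
    return(if (label == "malignant") 1 else -1)
  }
  label <- as.numeric(label)
  if (!label %in% c(-1, 1)) stop("label must be -1 (benign) or +1 (malignant)")
  label
}

#' @export
print.labeled_roi <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabeled" else if (x$label > 0) "malignant" else "benign"
  cat(sprintf("<labeled_roi %dx%d px, %s, source '%s'>\n",
              x$side_px, x$side_px, lab, x$source_id))
  invisible(x)
}

#' Extract a square ROI around an annotated mass
#'
#' Crops a square region around the mass centroid according to one of two
#' selection policies. `min_size_crop`: masses whose bounding square
#' (side = 2 * radius) is smaller than `min_side` are rejected; qualifying
#' masses get a `min_side` x `min_side` center crop about the centroid.
#' `resample`: the full `2 * radius` bounding square (including background)
#' is cropped and bilinearly resampled to `target_side` pixels. Crops that
#' overrun the image border are taken from a mirror-padded image, preserving
#' local texture statistics.
#'
#' @param image Numeric matrix of intensities in \[0, 1\] (rows = y,
#'   columns = x).
#' @param centroid_xy Length-2 vector `(x, y)` of 0-based pixel coordinates
#'   of the mass centroid (x = column, y = row).
#' @param radius_px Mass radius in pixels (> 0).
#' @param label Class label passed through to the ROI (may be `NA`).
#' @param policy `"min_size_crop"` or `"resample"`.
#' @param min_side Minimum/required crop side for `min_size_crop`.
#' @param target_side Output side for `resample`.
#' @param source_id Identifier propagated to the ROI.
#' @return A [labeled_roi], or `NULL` when the mass is rejected by the
#'   minimum-size criterion.
#' @export
extract_roi <- function(image, centroid_xy, radius_px, label = NA,
                        policy = c("min_size_crop", "resample"),
                        min_side = 64L, target_side = 128L, source_id = "") {
  policy <- match.arg(policy)
  image <- as.matrix(image)
  if (radius_px <= 0) stop("radius_px must be positive")
  cx <- centroid_xy[[1]]; cy <- centroid_xy[[2]]
  if (cx < 0 || cy < 0 || cx > ncol(image) - 1 || cy > nrow(image) - 1) {
    stop("annotation centroid (", cx, ", ", cy, ") outside image bounds")
  }
  if (policy == "min_size_crop") {
    if (2 * radius_px < min_side) return(NULL)  # rejected: mass too small
    side <- as.integer(min_side)
  } else {
    side <- max(2L, as.integer(round(2 * radius_px)))
  }
  crop <- center_crop(image, cx, cy, side)
  if (policy == "resample") crop <- resample_bilinear(crop, as.integer(target_side))
  labeled_roi(pmin(pmax(crop, 0), 1), label = label, source_id = source_id)
}

# side x side crop centered at 0-based (cx, cy); mirror-pads when the window
# overruns the image border.
center_crop <- function(image, cx, cy, side) {
  r0 <- as.integer(round(cy)) - side %/% 2L   # 0-based top row
  c0 <- as.integer(round(cx)) - side %/% 2L
  rows <- mirror_index(r0 + seq_len(side) - 1L, nrow(image))
  cols <- mirror_index(c0 + seq_len(side) - 1L, ncol(image))
  image[rows + 1L, cols + 1L, drop = FALSE]
}

# Reflect 0-based indices into [0, n-1] (mirror boundary, no edge repeat
# beyond one reflection period).
mirror_index <- function(idx, n) {
  if (n == 1L) return(rep(0L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- ((idx %% period) + period) %% period
  ifelse(idx >= n, period - idx, idx)
}

# Bilinear resampling of a matrix to target x target (area-aligned corners).
resample_bilinear <- function(M, target) {
  n_in <- nrow(M); m_in <- ncol(M)
  if (target == n_in && target == m_in) return(M)
  # map output pixel centers onto input pixel-center coordinates
  coord <- function(n_out, n_src) {
    if (n_out == 1L) return(0)
    (seq_len(n_out) - 1) * (n_src - 1) / (n_out - 1)
  }
  ry <- coord(target, n_in); rx <- coord(target, m_in)
  y0 <- pmin(floor(ry), n_in - 2); x0 <- pmin(floor(rx), m_in - 2)
  fy <- ry - y0; fx <- rx - x0
  out <- matrix(0, target, target)
  for (j in seq_len(target)) {
    c0 <- x0[j] + 1L; wx <- fx[j]
    col_lo <- M[, c0] * (1 - wx) + M[, c0 + 1L] * wx
    out[, j] <- col_lo[y0 + 1L] * (1 - fy) + col_lo[y0 + 2L] * fy
  }
  out
}

#' Decompose a ROI into a spatially ordered block grid
#'
#' Splits the square ROI into non-overlapping `m` x `n` pixel blocks and
#' vectorizes each. The ordering convention is fixed package-wide: pixels
#' within a block are vectorized column-major; blocks are enumerated
#' row-major over the grid (lexicographic order).
#'
#' @param roi A [labeled_roi] or a square numeric matrix.
#' @param block_shape Length-2 integer vector `(m, n)` = (rows, cols) of a
#'   block. The ROI side must be divisible by both.
#' @return An object of class `block_grid` with `blocks` (a `m*n` x `NB`
#'   matrix, one column per block), `block_shape`, `grid_shape`, `side_px`.
#' @export
decompose <- function(roi, block_shape) {
  px <- if (inherits(roi, "labeled_roi")) roi$pixels else as.matrix(roi)
  side <- nrow(px)
  if (side != ncol(px)) stop("ROI must be square")
  m <- as.integer(block_shape[[1]]); n <- as.integer(block_shape[[2]])
  if (m < 1 || n < 1) stop("block dimensions must be positive")
  if (side %% m != 0 || side %% n != 0) {
    stop("ROI side ", side, " not divisible by block shape ", m, "x", n)
  }
  g_rows <- side %/% m; g_cols <- side %/% n
  nb <- g_rows * g_cols
  blocks <- matrix(0, m * n, nb)
  k <- 0L
  for (gr in seq_len(g_rows)) {        # row-major over the grid
    for (gc in seq_len(g_cols)) {
      k <- k + 1L
      blocks[, k] <- as.vector(px[(gr - 1L) * m + seq_len(m),
                                  (gc - 1L) * n + seq_len(n)])
    }
  }
  structure(
    list(blocks = blocks, block_shape = c(m, n),
         grid_shape = c(g_rows, g_cols), side_px = side),
    class = "block_grid"
  )
}

#' Reassemble a block grid into the original ROI
#'
#' Exact inverse of [decompose()]: bit-identical pixels.
#'
#' @param grid A `block_grid`.
#' @return Numeric matrix of side `side_px`.
#' @export
reassemble <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  m <- grid$block_shape[1]; n <- grid$block_shape[2]
  g_rows <- grid$grid_shape[1]; g_cols <- grid$grid_shape[2]
  if (ncol(grid$blocks) != g_rows * g_cols) {
    stop("block count ", ncol(grid$blocks), " inconsistent with grid shape")
  }
  if (nrow(grid$blocks) != m * n) stop("block vector length inconsistent with block shape")
  px <- matrix(0, grid$side_px, grid$side_px)
  k <- 0L
  for (gr in seq_len(g_rows)) {
    for (gc in seq_len(g_cols)) {
      k <- k + 1L
      px[(gr - 1L) * m + seq_len(m), (gc - 1L) * n + seq_len(n)] <-
        matrix(grid$blocks[, k], m, n)
    }
  }
  px
}

#' Build per-position block training matrices
#'
#' For every block position j, stacks block j of each training ROI as the
#' columns of a training matrix (the raw, unlearned block dictionary), with
#' column labels aligned to the ROIs.
#'
#' @param rois List of [labeled_roi] objects, all with the same side and
#'   non-`NA` labels.
#' @param block_shape `(m, n)` block shape.
#' @param require_both_classes Error unless both classes are present
#'   (needed by all learning modes); set `FALSE` for diagnostics only.
#' @return List of length NB; element j is a list with `block_index`, `Y`
#'   (d x s matrix), `column_labels` (length s), `block_shape`, `side_px`.
#' @export
build_block_training_matrices <- function(rois, block_shape,
                                          require_both_classes = TRUE) {
  if (length(rois) == 0) stop("empty ROI list")
  sides <- vapply(rois, function(r) r$side_px, numeric(1))
  if (length(unique(sides)) != 1) stop("mixed ROI sizes: ", paste(unique(sides), collapse = ", "))
  labels <- vapply(rois, function(r) r$label, numeric(1))
  if (anyNA(labels)) stop("all training ROIs must be labeled")
  if (require_both_classes && length(unique(labels)) < 2) {
    stop("training set must contain both classes")
  }
  grids <- lapply(rois, decompose, block_shape = block_shape)
  nb <- ncol(grids[[1]]$blocks)
  lapply(seq_len(nb), function(j) {
    Y <- vapply(grids, function(g) g$blocks[, j], numeric(nrow(grids[[1]]$blocks)))
    list(block_index = j, Y = as.matrix(Y), column_labels = labels,
         block_shape = grids[[1]]$block_shape, side_px = sides[1])
  })
}
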