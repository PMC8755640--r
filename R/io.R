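#' Read a grayscale raster image
#'
#' Reads PNG, TIFF or PGM rasters into a numeric matrix with intensities
#' rescaled to \[0, 1\] (any bit depth). Color inputs are converted to
#' luminance by channel averaging.
#'
#' @param path File path; format inferred from the extension.
#' @return Numeric matrix (rows = y, columns = x), values in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img <- as.matrix(img)
  # png/tiff readers already scale to [0,1]; guard against stray values
  pmin(pmax(img, 0), 1)
}

# Minimal PGM (P2 ascii / P5 binary, maxval <= 65535) reader; no installed
# package handles this format.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE); if (!length(c2) || c2 == "\n") break } }
      else if (!grepl("^[ \t\r\n]$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("^[ \t\r\n]$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(token()); h <- as.integer(token()); maxval <- as.integer(token())
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated PGM pixel data")
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale matrix as 8-bit PNG
#' @param pixels Matrix with values in \[0, 1\].
#' @param path Output path.
#' @export
write_gray_png <- function(pixels, path) {
  png::writePNG(pmin(pmax(as.matrix(pixels), 0), 1), target = path)
  invisible(path)
}

#' Read a mass annotation table
#'
#' CSV with header `image_path,centroid_x,centroid_y,radius_px,label`;
#' coordinates are 0-based pixel indices (x = column, y = row), labels
#' `benign`/`malignant`.
#'
#' @param path CSV path.
#' @return data.frame with those columns, labels normalized to -1/+1 in an
#'   extra `label_num` column.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_path", "centroid_x", "centroid_y", "radius_px", "label")
  missing <- setdiff(required, names(ann))
  if (length(missing)) stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  if (any(ann$radius_px <= 0)) stop("radius_px must be positive")
  ann$label_num <- vapply(ann$label, normalize_label, numeric(1))
  ann
}

#' Load a labeled ROI dataset from images + annotations
#'
#' Runs the full ingestion path: read each annotated image, extract its ROI
#' per the chosen policy, and return the kept ROIs. Masses rejected by the
#' minimum-size criterion are dropped (reported in an attribute).
#'
#' @param annotations data.frame from [read_annotations()] or a path to the
#'   CSV. Relative `image_path`s are resolved against `image_dir`.
#' @param image_dir Base directory for relative image paths.
#' @inheritParams extract_roi
#' @return List of [labeled_roi]; attribute `rejected` holds the row indices
#'   of rejected masses.
#' @export
load_roi_dataset <- function(annotations, image_dir = ".",
                             policy = c("min_size_crop", "resample"),
                             min_side = 64L, target_side = 128L) {
  policy <- match.arg(policy)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  rois <- list(); rejected <- integer()
  for (i in seq_len(nrow(annotations))) {
    row <- annotations[i, ]
    p <- if (file.exists(row$image_path)) row$image_path else file.path(image_dir, row$image_path)
    img <- read_gray_image(p)
    roi <- extract_roi(img, c(row$centroid_x, row$centroid_y), row$radius_px,
                       label = row$label_num, policy = policy,
                       min_side = min_side, target_side = target_side,
                       source_id = basename(row$image_path))
    if (is.null(roi)) rejected <- c(rejected, i) else rois[[length(rois) + 1L]] <- roi
  }
  attr(rois, "rejected") <- rejected
  rois
}
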