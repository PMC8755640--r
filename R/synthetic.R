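# Synthetic two-class textured-mass ROIs. Each ROI is a centered
# soft-edged disc over a uniform background, modulated by an oriented
# sinusoidal texture whose frequency/orientation are class-conditional, plus
# i.i.d. Gaussian intensity noise. The class structure is block-stationary
# by construction, matching the positional-dictionary assumption, and the
# difficulty of the classification task is controlled by the gap between
# the class texture frequencies.

#' Synthetic dataset configuration
#'
#' Defaults describe two texture classes on 64 x 64 px ROIs that differ
#' only in texture frequency (4 vs 14 cycles per ROI side); orientation,
#' disc size and contrast are identical across classes so that the spectral
#' content alone carries class information.
#'
#' @param side_px ROI side in pixels (power of two >= 32).
#' @param benign,malignant Per-class spec: list with `texture_frequency`
#'   (cycles per ROI side), `orientation` (radians), `blob_contrast`
#'   (\[0, 1\] additive disc contrast), `blob_radius_frac` (disc radius as a
#'   fraction of side/2).
#' @param texture_amplitude Amplitude of the sinusoidal modulation
#'   (intensity units).
#' @param background Background intensity.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param n_benign,n_malignant Samples per class.
#' @param seed RNG seed; the whole dataset is a pure function of the
#'   configuration.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(side_px = 64L,
                             benign = list(texture_frequency = 4,
                                           orientation = pi / 4,
                                           blob_contrast = 0.25,
                                           blob_radius_frac = 0.6),
                             malignant = list(texture_frequency = 14,
                                              orientation = pi / 4,
                                              blob_contrast = 0.25,
                                              blob_radius_frac = 0.6),
                             texture_amplitude = 0.15,
                             background = 0.35,
                             noise_sigma = 0.05,
                             n_benign = 36L, n_malignant = 37L,
                             seed = 1L) {
  side_px <- as.integer(side_px)
  if (side_px < 32L || bitwAnd(side_px, side_px - 1L) != 0L) {
    stop("side_px must be a power of two >= 32")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (spec in list(benign, malignant)) {
    stopifnot(spec$blob_contrast >= 0, spec$blob_contrast <= 1,
              spec$blob_radius_frac > 0, spec$blob_radius_frac < 1)
  }
  if (identical(benign, malignant)) {
    warning("class specs are identical; classes are indistinguishable")
  }
  structure(list(side_px = side_px,
                 class_specs = list(`-1` = benign, `1` = malignant),
                 texture_amplitude = texture_amplitude,
                 background = background, noise_sigma = noise_sigma,
                 n_per_class = c(`-1` = as.integer(n_benign),
                                 `1` = as.integer(n_malignant)),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic ROI
#'
#' Deterministic given `(config, class, index)`: the per-ROI RNG stream is
#' derived from the configuration seed, the class and the sample index.
#'
#' @param class `-1` (benign) or `+1` (malignant).
#' @param config A [synthetic_config()].
#' @param index Sample index within the class (governs the random texture
#'   phase and the noise draw).
#' @return A [labeled_roi()].
#' @export
generate_roi <- function(class, config, index = 1L) {
  key <- as.character(normalize_label(class))
  spec <- config$class_specs[[key]]
  if (is.null(spec)) stop("unknown class: ", class)
  s <- config$side_px
  with_seed(derive_seed(config$seed, if (key == "1") 2L else 1L, index), {
    phase <- stats::runif(1, 0, 2 * pi)
    # pixel-center coordinates in [0, 1]
    u <- (seq_len(s) - 0.5) / s
    xs <- matrix(u, s, s, byrow = TRUE)
    ys <- matrix(u, s, s)
    wave <- sin(2 * pi * spec$texture_frequency *
                  (xs * cos(spec$orientation) + ys * sin(spec$orientation)) + phase)
    r <- sqrt((xs - 0.5)^2 + (ys - 0.5)^2)       # radial distance, units of side
    radius <- spec$blob_radius_frac * 0.5
    edge <- 0.1 * radius + 1e-9                   # soft edge width
    disc <- pmin(pmax((radius - r) / edge, 0), 1) # ramped indicator
    px <- config$background + spec$blob_contrast * disc +
      config$texture_amplitude * wave
    if (config$noise_sigma > 0) {
      px <- px + matrix(stats::rnorm(s * s, sd = config$noise_sigma), s, s)
    }
    labeled_roi(pmin(pmax(px, 0), 1), label = as.numeric(key),
                source_id = sprintf("synth_%s_%03d",
                                    if (key == "1") "malignant" else "benign",
                                    index))
  })
}

#' Generate a labeled synthetic dataset
#'
#' `n_benign` + `n_malignant` ROIs, deterministically shuffled.
#'
#' @param config A [synthetic_config()].
#' @return List of [labeled_roi()] objects.
#' @export
generate_dataset <- function(config) {
  stopifnot(all(config$n_per_class >= 1))
  rois <- c(
    lapply(seq_len(config$n_per_class[["-1"]]), function(i) generate_roi(-1, config, i)),
    lapply(seq_len(config$n_per_class[["1"]]), function(i) generate_roi(1, config, i))
  )
  perm <- with_seed(derive_seed(config$seed, 777L), sample(length(rois)))
  rois[perm]
}

#' Write a synthetic dataset as PNG files + annotation CSV
#'
#' Materializes the dataset through the package's real ingestion format:
#' one 8-bit grayscale PNG per ROI and a CSV with columns
#' `image_path,centroid_x,centroid_y,radius_px,label` (centroid = image
#' center, radius = disc radius), so the files can be re-read with
#' [load_roi_dataset()].
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Path of the annotation CSV, invisibly.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rois <- generate_dataset(config)
  rows <- lapply(rois, function(r) {
    fname <- paste0(r$source_id, ".png")
    write_gray_png(r$pixels, file.path(dir, fname))
    key <- as.character(r$label)
    data.frame(image_path = fname,
               centroid_x = (r$side_px - 1) / 2,
               centroid_y = (r$side_px - 1) / 2,
               radius_px = config$class_specs[[key]]$blob_radius_frac * r$side_px / 2,
               label = if (r$label > 0) "malignant" else "benign",
               stringsAsFactors = FALSE)
  })
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
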