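#' Save a trained model to a directory archive
#'
#' Writes `manifest.json` (mode, block shape, ROI side, configuration,
#' package version) plus `blocks.rds` holding, for every block index, the
#' dense matrices `D`, the atom labels and, for LC models, `A` and `W`.
#' Reload with [load_slesa_model()] is bit-exact.
#'
#' @param model A `slesa_model`.
#' @param dir Target directory (created; must not already contain a model
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing archive.
#' @return `dir`, invisibly.
#' @export
save_slesa_model <- function(model, dir, overwrite = FALSE) {
  stopifnot(inherits(model, "slesa_model"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("model archive already exists at ", dir, " (use overwrite = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "slesa_model", format_version = 1L,
    package_version = as.character(utils::packageVersion("slesa")),
    mode = model$mode, block_shape = model$block_shape,
    side_px = model$side_px, n_blocks = length(model$dictionaries),
    config = unclass(model$config)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  saveRDS(model$dictionaries, file.path(dir, "blocks.rds"), version = 3)
  invisible(dir)
}

#' Load a model archive written by [save_slesa_model()]
#'
#' @param dir Archive directory.
#' @return A `slesa_model` identical to the saved one.
#' @export
load_slesa_model <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no model manifest at ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "slesa_model")) stop("not a slesa model archive")
  dicts <- readRDS(file.path(dir, "blocks.rds"))
  if (length(dicts) != manifest$n_blocks) stop("corrupt archive: block count mismatch")
  cfg <- manifest$config
  config <- slesa_config(n_atoms_per_class = cfg$n_atoms_per_class,
                         T_sparsity = cfg$T_sparsity, eps = cfg$eps,
                         alpha = cfg$alpha, beta = cfg$beta,
                         n_iter = cfg$n_iter, seed = cfg$seed)
  structure(list(dictionaries = dicts,
                 block_shape = as.integer(manifest$block_shape),
                 side_px = as.integer(manifest$side_px),
                 mode = manifest$mode, config = config),
            class = "slesa_model")
}
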