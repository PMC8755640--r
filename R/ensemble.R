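# Block-based ensemble decision functions. Per block, the class evidence is
# a signed log-likelihood computed either from the class-wise L1 coefficient
# masses (sparsity score, the "-S" rules) or from the class-restricted
# reconstruction residuals (residual score, the "-R" rules). Scores are
# oriented so that a positive value favors class m; with the package label
# convention m = malignant (+1), n = benign (-1). Degenerate masses and
# residuals are floored at `kappa` before taking the ratio, which keeps all
# scores finite without affecting the ranking of non-degenerate cases.

SCORE_FLOOR <- 1e-12

#' Sparsity-based block log-likelihood score
#'
#' `log(||delta_m(x)||_1 / ||delta_n(x)||_1)` with both masses floored at
#' `1e-12`: positive when the atoms of class `class_m` carry more of the
#' code's L1 mass, i.e. evidence for class m. An all-zero code scores 0.
#'
#' @param code A `sparse_code` with `per_class_l1` (coded against a labeled
#'   dictionary).
#' @param class_m,class_n The two class labels (defaults: malignant +1 vs
#'   benign -1).
#' @return Signed scalar; `>= 0` favors `class_m`.
#' @export
lls_score <- function(code, class_m = 1, class_n = -1) {
  masses <- code$per_class_l1
  if (is.null(masses)) stop("code lacks per-class L1 masses (unlabeled dictionary?)")
  # difference of logs rather than log of the ratio: label-flip
  # antisymmetry is then exact in floating point
  log(max(masses[[as.character(class_m)]], SCORE_FLOOR)) -
    log(max(masses[[as.character(class_n)]], SCORE_FLOOR))
}

#' Residual-based block log-likelihood score
#'
#' `-log(r_m / r_n)` where `r_c = ||D delta_c(x) - y||_2` is the
#' class-restricted reconstruction residual (floored at `1e-12`): positive
#' when class m's atoms reconstruct the block better (smaller residual).
#'
#' @param code A `sparse_code` with `per_class_residual`.
#' @inheritParams lls_score
#' @return Signed scalar; `>= 0` favors `class_m`.
#' @export
llr_score <- function(code, class_m = 1, class_n = -1) {
  res <- code$per_class_residual
  if (is.null(res)) stop("code lacks per-class residuals (unlabeled dictionary?)")
  log(max(res[[as.character(class_n)]], SCORE_FLOOR)) -
    log(max(res[[as.character(class_m)]], SCORE_FLOOR))
}

#' Mean block log-likelihood
#'
#' Arithmetic mean of the per-block signed scores — the ensemble's estimate
#' of the expected block log-likelihood (ELL).
#'
#' @param scores Numeric vector of NB block scores (NB >= 1).
#' @return Scalar mean.
#' @export
ell <- function(scores) {
  if (length(scores) == 0) stop("empty block score sequence")
  mean(scores)
}

#' Block-based log-likelihood (BBLL) decision
#'
#' Maps the mean block log-likelihood through the shifted sigmoid
#' `score = tanh(ell - tau)` in \[-1, 1\] and takes the decision from its
#' sign; a score of exactly 0 is assigned to the benign class (conservative
#' with respect to false positives).
#'
#' @param ell_value Mean block log-likelihood.
#' @param tau Shift parameter compensating classification bias (default 0).
#' @param rule Decision-function tag stored in the result.
#' @param block_scores Optional per-block scores kept for audit.
#' @return Object of class `ensemble_decision` with `label` (-1/+1),
#'   `score` in \[-1, 1\], `ell`, `tau`, `rule`.
#' @export
bbll_decide <- function(ell_value, tau = 0, rule = "BBLL-S", block_scores = NULL) {
  stopifnot(is.finite(tau))
  score <- tanh(ell_value - tau)
  label <- if (score > 0) 1 else -1
  structure(list(label = label, score = score, ell = ell_value,
                 posterior = NULL, tau = tau, rule = rule,
                 block_scores = block_scores),
            class = "ensemble_decision")
}

#' Block-based majority-vote (BBMAP) decision
#'
#' The class posterior is the empirical vote fraction over the NB per-block
#' hard labels; the decision is the majority class. Ties are broken by the
#' sign of the summed block scores, and toward benign if that is also zero.
#'
#' @param block_labels Vector of NB hard labels in \{-1, +1\}.
#' @param block_scores Optional signed block scores (used for tie-breaks
#'   and as the continuous score).
#' @param rule Decision-function tag.
#' @return `ensemble_decision` with `posterior` = malignant vote fraction
#'   and `score` = 2 * posterior - 1 in \[-1, 1\].
#' @export
bbmap_decide <- function(block_labels, block_scores = NULL, rule = "BBMAP-S") {
  if (length(block_labels) == 0) stop("empty block label sequence")
  if (!all(block_labels %in% c(-1, 1))) stop("block labels must be -1/+1")
  post_mal <- mean(block_labels == 1)
  label <- if (post_mal > 0.5) 1 else if (post_mal < 0.5) -1 else {
    s <- if (is.null(block_scores)) 0 else sum(block_scores)
    if (s > 0) 1 else -1
  }
  structure(list(label = label, score = 2 * post_mal - 1,
                 ell = if (is.null(block_scores)) NA_real_ else mean(block_scores),
                 posterior = post_mal, tau = 0, rule = rule,
                 block_scores = block_scores),
            class = "ensemble_decision")
}

#' @export
print.ensemble_decision <- function(x, ...) {
  cat(sprintf("<%s: %s (score %.4f%s)>\n", x$rule,
              if (x$label > 0) "malignant" else "benign", x$score,
              if (!is.null(x$posterior)) sprintf(", posterior %.3f", x$posterior) else ""))
  invisible(x)
}

#' Train a SLESA / LS-SLESA / LC-SLESA model
#'
#' Builds one dictionary per block position from the labeled training ROIs.
#' `mode = "slesa"`: the raw training blocks (unit-normalized) are the
#' atoms, labeled by their source ROI. `mode = "ls"`: label-separated KSVD
#' per class. `mode = "lc"`: label-consistent KSVD2.
#'
#' @param rois List of labeled [labeled_roi] objects (same side, both
#'   classes present).
#' @param block_shape `(m, n)` block shape; the ROI side must be divisible
#'   by both. Block shape equal to the ROI side degenerates to conventional
#'   single-dictionary SRC.
#' @param mode `"slesa"`, `"ls"` or `"lc"`.
#' @param config A [slesa_config()].
#' @return Object of class `slesa_model`: `dictionaries` (list of
#'   [block_dictionary()]), `block_shape`, `side_px`, `mode`, `config`.
#' @export
slesa_train <- function(rois, block_shape, mode = c("slesa", "ls", "lc"),
                        config = slesa_config()) {
  mode <- match.arg(mode)
  blocks <- build_block_training_matrices(rois, block_shape)
  dicts <- lapply(blocks, function(b) {
    switch(mode,
      slesa = {
        keep <- colSums(b$Y^2) > 0
        if (!any(keep)) stop("block ", b$block_index, ": all training blocks are zero")
        block_dictionary(b$Y[, keep, drop = FALSE], b$column_labels[keep],
                         block_index = b$block_index)
      },
      ls = ls_learn(b, config),
      lc = lc_learn(b, config)
    )
  })
  structure(list(dictionaries = dicts,
                 block_shape = blocks[[1]]$block_shape,
                 side_px = blocks[[1]]$side_px,
                 mode = mode, config = config),
            class = "slesa_model")
}

#' @export
print.slesa_model <- function(x, ...) {
  cat(sprintf("<slesa_model mode=%s, ROI %dx%d, %dx%d blocks, %d dictionaries>\n",
              x$mode, x$side_px, x$side_px, x$block_shape[1], x$block_shape[2],
              length(x$dictionaries)))
  invisible(x)
}

#' Classify one ROI with a trained model
#'
#' Decomposes the ROI with the model's block shape, sparse-codes every
#' block against its positional dictionary (OMP with the model's sparsity
#' and residual tolerance unless overridden), computes the per-block signed
#' scores, and fuses them with the requested decision function. Zero-norm
#' blocks code to zero and contribute a neutral (zero) score.
#'
#' @param roi A [labeled_roi] or square matrix (label ignored).
#' @param model A `slesa_model`.
#' @param rule One of `"bbll-s"`, `"bbll-r"`, `"bbmap-s"`, `"bbmap-r"`.
#' @param tau Shift parameter for the BBLL rules.
#' @param T_sparsity,eps Optional overrides of the model's coding
#'   parameters.
#' @return An `ensemble_decision` with per-block scores attached.
#' @export
classify_roi <- function(roi, model, rule = c("bbll-s", "bbll-r", "bbmap-s", "bbmap-r"),
                         tau = 0, T_sparsity = NULL, eps = NULL) {
  rule <- match.arg(rule)
  T_sparsity <- T_sparsity %||% model$config$T_sparsity
  eps <- eps %||% model$config$eps
  grid <- decompose(roi, model$block_shape)
  if (ncol(grid$blocks) != length(model$dictionaries)) {
    stop("ROI block count ", ncol(grid$blocks), " does not match model (",
         length(model$dictionaries), ")")
  }
  use_resid <- rule %in% c("bbll-r", "bbmap-r")
  scores <- vapply(seq_along(model$dictionaries), function(j) {
    code <- omp(model$dictionaries[[j]], grid$blocks[, j], T_sparsity, eps)
    if (use_resid) llr_score(code) else lls_score(code)
  }, numeric(1))
  if (startsWith(rule, "bbll")) {
    bbll_decide(ell(scores), tau = tau,
                rule = toupper(rule), block_scores = scores)
  } else {
    hard <- ifelse(scores > 0, 1, -1)
    bbmap_decide(hard, block_scores = scores, rule = toupper(rule))
  }
}

#' Classify a batch of ROIs into a report table
#'
#' @param rois List of ROIs (labels, if present, are copied into the
#'   report's `true_label` column).
#' @inheritParams classify_roi
#' @return data.frame with one row per ROI: `source_id`, `rule`, `ell`,
#'   `score`, `posterior`, `label`, `true_label`.
#' @export
classify_batch <- function(rois, model, rule = "bbll-s", tau = 0,
                           T_sparsity = NULL, eps = NULL) {
  rows <- lapply(rois, function(r) {
    dec <- classify_roi(r, model, rule = rule, tau = tau,
                        T_sparsity = T_sparsity, eps = eps)
    data.frame(source_id = if (inherits(r, "labeled_roi")) r$source_id else "",
               rule = dec$rule, ell = dec$ell, score = dec$score,
               posterior = dec$posterior %||% NA_real_, label = dec$label,
               true_label = if (inherits(r, "labeled_roi")) r$label else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
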