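# Evaluation machinery: stratified k-fold cross-validation, confusion
# metrics, trapezoidal ROC/AUC (equal to the Mann-Whitney concordance
# estimator with ties counted 1/2), DeLong's paired AUC test, and
# exhaustive grid search. Malignant (+1) is the positive class throughout.

#' Stratified fold assignment
#'
#' Assigns every sample to one of `k` folds, stratified by class: within
#' each class, indices are shuffled (seeded) and dealt round-robin, so
#' per-fold class counts differ by at most one from proportionality.
#'
#' @param labels Class label (-1/+1) per sample.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed; the plan is deterministic given (labels, k, seed).
#' @param allow_small Permit `k` larger than the minority-class count
#'   (some folds then lack a class and pooled scoring is required).
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(labels, k, seed = 1L, allow_small = FALSE) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  n_min <- min(table(labels))
  if (k > n_min && !allow_small) {
    stop("k = ", k, " exceeds the minority class count (", n_min,
         "); set allow_small = TRUE to override")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    cursor <- 0L  # continue dealing across classes so fold totals stay even
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample(length(idx))]
      folds[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- (cursor + length(idx)) %% k
    }
  })
  folds
}

#' Confusion and ranking metrics
#'
#' TPR (sensitivity), TNR (specificity) and ACC come from the confusion
#' matrix at the operating point `score > threshold` => malignant; AUC is
#' the area under the trapezoidal ROC over all score thresholds, which
#' equals the Mann-Whitney two-sample concordance statistic with ties
#' counted one half.
#'
#' @param true_labels Vector in \{-1, +1\} with both classes present.
#' @param scores Continuous classifier scores (larger => more malignant).
#' @param threshold Operating threshold on the scores (default 0; exact
#'   ties go to benign).
#' @return List of class `metric_report`: `tpr`, `tnr`, `acc`, `auc`,
#'   `roc` (data.frame fpr/tpr), and the confusion counts.
#' @export
compute_metrics <- function(true_labels, scores, threshold = 0) {
  if (length(true_labels) != length(scores)) stop("labels/scores length mismatch")
  if (anyNA(scores) || anyNA(true_labels)) stop("NA in labels or scores")
  pos <- true_labels == 1
  if (!any(pos) || all(pos)) stop("AUC undefined: both classes required")
  pred <- ifelse(scores > threshold, 1, -1)
  tp <- sum(pred == 1 & pos); fn <- sum(pred == -1 & pos)
  tn <- sum(pred == -1 & !pos); fp <- sum(pred == 1 & !pos)
  roc <- roc_points(true_labels, scores)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(tpr = tp / (tp + fn), tnr = tn / (tn + fp),
                 acc = (tp + tn) / length(scores), auc = auc, roc = roc,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("TPR %.4f  TNR %.4f  ACC %.4f  AUC %.4f\n",
              x$tpr, x$tnr, x$acc, x$auc))
  invisible(x)
}

# ROC curve points sweeping the threshold from +Inf down; tied scores are
# grouped so the trapezoid over the curve equals the concordance AUC.
roc_points <- function(true_labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- true_labels[ord]; sc <- scores[ord]
  n_pos <- sum(lab == 1); n_neg <- sum(lab == -1)
  grp_end <- which(!duplicated(sc, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(lab == 1)[grp_end]
  fp <- cumsum(lab == -1)[grp_end]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

# Placement values of DeLong: for each positive, the fraction of negatives
# it beats (ties 1/2), and vice versa.
delong_placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two paired AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples
#' using the DeLong placement-value covariance estimate and a two-sided
#' normal approximation for the AUC difference.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param true_labels Shared truth in \{-1, +1\}, both classes present.
#' @return List: `auc_a`, `auc_b`, `z`, `p_value`, `degenerate` (TRUE when
#'   the variance of the difference vanishes, in which case `p_value` = 1
#'   with a warning).
#' @export
delong_test <- function(scores_a, scores_b, true_labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(true_labels)) stop("paired inputs required")
  pos <- true_labels == 1
  if (!any(pos) || all(pos)) stop("both classes required")
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(var_diff) || var_diff <= 0) {
    if (pa$auc != pb$auc) warning("degenerate DeLong variance with unequal AUCs")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

# Calibrate the BBLL shift on training-fold ELL values: pick, over a
# 101-point grid of training ELL quantiles, the shift maximizing balanced
# accuracy (ties -> smallest shift).
calibrate_shift <- function(ell_values, labels) {
  grid <- unique(stats::quantile(ell_values, probs = seq(0, 1, length.out = 101),
                                 names = FALSE, type = 7))
  bal <- vapply(grid, function(t) {
    pred <- ifelse(ell_values > t, 1, -1)
    (mean(pred[labels == 1] == 1) + mean(pred[labels == -1] == -1)) / 2
  }, numeric(1))
  grid[which.max(bal)]
}

#' Cross-validated evaluation of a SLESA variant
#'
#' Stratified k-fold protocol with no leakage: for each fold, dictionaries
#' (and, when enabled, the BBLL shift tau) are learned strictly on the
#' training folds, and the held-out ROIs are scored. Scores are pooled over
#' folds for the reported metrics.
#'
#' @param rois Labeled ROI list.
#' @param block_shape Block shape `(m, n)`.
#' @param mode `"slesa"`, `"ls"` or `"lc"`.
#' @param rule Decision rule (see [classify_roi()]).
#' @param config A [slesa_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold plan.
#' @param calibrate_tau Calibrate the BBLL shift per fold on training ELLs
#'   (default `FALSE`: tau = 0).
#' @return List of class `cv_result`: pooled `metrics`, per-sample `table`
#'   (fold, true/predicted label, score), `folds`, and the arguments.
#' @export
cross_validate <- function(rois, block_shape, mode = "slesa", rule = "bbll-s",
                           config = slesa_config(), k = 10L, seed = 1L,
                           calibrate_tau = FALSE) {
  labels <- vapply(rois, function(r) r$label, numeric(1))
  folds <- make_folds(labels, k, seed = seed, allow_small = TRUE)
  rows <- vector("list", length(rois))
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    if (length(test_idx) == 0) next
    train <- rois[folds != f]
    model <- slesa_train(train, block_shape, mode = mode, config = config)
    tau <- 0
    if (calibrate_tau && startsWith(rule, "bbll")) {
      train_ell <- vapply(train, function(r) {
        classify_roi(r, model, rule = rule)$ell
      }, numeric(1))
      tau <- calibrate_shift(train_ell, vapply(train, `[[`, numeric(1), "label"))
    }
    for (i in test_idx) {
      dec <- classify_roi(rois[[i]], model, rule = rule, tau = tau)
      rows[[i]] <- data.frame(index = i, fold = f,
                              true_label = labels[i], label = dec$label,
                              score = if (startsWith(rule, "bbll")) dec$ell - tau else dec$score,
                              tau = tau, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  metrics <- compute_metrics(table$true_label, table$score)
  structure(list(metrics = metrics, table = table, folds = folds,
                 mode = mode, rule = rule, block_shape = block_shape,
                 k = k, config = config, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s / %s, %dx%d blocks, %d-fold CV\n", toupper(x$mode),
              toupper(x$rule), x$block_shape[1], x$block_shape[2], x$k))
  print(x$metrics)
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Cross-validates every combination of the supplied grids and selects the
#' best configuration by AUC, with ACC as the tie-break. Default grids are
#' `eps` in \{0.001, 0.01, 0.1, 0.5\}, sparsity `T` in \{1, 5, 10, 30, 60\}
#' (learning modes), and `(alpha, beta)` in \{(4e-4, 2e-4), (4e-3, 2e-3),
#' (0.04, 0.02), (0.4, 0.2)\} (LC mode).
#'
#' @inheritParams cross_validate
#' @param eps_grid,T_grid Numeric grids (T_grid is ignored for plain SLESA
#'   coding only in the sense that it still sets the coding sparsity).
#' @param atoms_grid Total dictionary sizes tried in learning modes.
#' @param alpha_beta_grid List of `c(alpha, beta)` pairs (LC mode only).
#' @param base_config Template [slesa_config()] supplying the fields not on
#'   a grid.
#' @return List of class `grid_search_result`: `best` (config + metrics)
#'   and `table` (one row per configuration).
#' @export
grid_search <- function(rois, block_shape, mode = "slesa", rule = "bbll-s",
                        eps_grid = c(0.001, 0.01, 0.1, 0.5),
                        T_grid = c(1, 5, 10, 30, 60),
                        atoms_grid = 60,
                        alpha_beta_grid = list(c(4e-4, 2e-4), c(4e-3, 2e-3),
                                               c(0.04, 0.02), c(0.4, 0.2)),
                        base_config = slesa_config(), k = 10L, seed = 1L) {
  if (!length(eps_grid) || !length(T_grid)) stop("empty grid")
  if (mode != "lc") alpha_beta_grid <- list(c(base_config$alpha, base_config$beta))
  if (mode == "slesa") atoms_grid <- base_config$n_atoms_per_class * 2
  combos <- expand.grid(eps = eps_grid, T_sparsity = T_grid,
                        n_atoms = atoms_grid,
                        ab = seq_along(alpha_beta_grid))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ab <- alpha_beta_grid[[combos$ab[i]]]
    cfg <- slesa_config(n_atoms_per_class = max(1L, floor(combos$n_atoms[i] / 2)),
                        T_sparsity = combos$T_sparsity[i], eps = combos$eps[i],
                        alpha = ab[1], beta = ab[2],
                        n_iter = base_config$n_iter, seed = base_config$seed)
    cv <- cross_validate(rois, block_shape, mode = mode, rule = rule,
                         config = cfg, k = k, seed = seed)
    rows[[i]] <- data.frame(eps = cfg$eps, T_sparsity = cfg$T_sparsity,
                            n_atoms = combos$n_atoms[i],
                            alpha = cfg$alpha, beta = cfg$beta,
                            tpr = cv$metrics$tpr, tnr = cv$metrics$tnr,
                            acc = cv$metrics$acc, auc = cv$metrics$auc)
  }
  table <- do.call(rbind, rows)
  best_i <- order(-table$auc, -table$acc)[1]
  ab <- c(table$alpha[best_i], table$beta[best_i])
  best_cfg <- slesa_config(n_atoms_per_class = max(1L, floor(table$n_atoms[best_i] / 2)),
                           T_sparsity = table$T_sparsity[best_i],
                           eps = table$eps[best_i], alpha = ab[1], beta = ab[2],
                           n_iter = base_config$n_iter, seed = base_config$seed)
  structure(list(best = list(config = best_cfg,
                             metrics = table[best_i, , drop = FALSE]),
                 table = table, mode = mode, rule = rule, k = k),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search (%s / %s, %d-fold): %d configurations\n",
              toupper(x$mode), toupper(x$rule), x$k, nrow(x$table)))
  cat("best:\n"); print(x$best$metrics, row.names = FALSE)
  invisible(x)
}
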