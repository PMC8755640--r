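# Dictionary learning: KSVD core, label-separated learning (one KSVD per
# class, dictionaries concatenated), and label-consistent KSVD2 via the
# stacked-data reduction (augment training data with the scaled
# discriminative code matrix Q and label matrix H, learn one augmented
# dictionary, then split and renormalize).

#' Block dictionary
#'
#' Dictionary of unit-norm atoms for one block position, with per-atom
#' class labels and, after label-consistent learning, the code transform
#' `A` and linear classifier `W`.
#'
#' @param atoms d x n matrix; columns are normalized to unit Euclidean norm.
#' @param atom_labels Length-n class label per atom (-1/+1).
#' @param block_index Spatial block position (lexicographic index).
#' @param A,W Optional LC-KSVD2 matrices (columns aligned with atoms).
#' @return Object of class `block_dictionary`.
#' @export
block_dictionary <- function(atoms, atom_labels, block_index = 1L,
                             A = NULL, W = NULL) {
  atoms <- as.matrix(atoms)
  nrm <- sqrt(colSums(atoms^2))
  fix <- which(nrm > 0 & abs(nrm - 1) > 1e-12)  # leave unit atoms untouched
  atoms[, fix] <- sweep(atoms[, fix, drop = FALSE], 2, nrm[fix], "/")
  if (length(atom_labels) != ncol(atoms)) stop("one label per atom required")
  if (!is.null(A) && ncol(A) != ncol(atoms)) stop("A column count must equal atom count")
  if (!is.null(W) && ncol(W) != ncol(atoms)) stop("W column count must equal atom count")
  structure(list(block_index = as.integer(block_index), atoms = atoms,
                 atom_labels = as.numeric(atom_labels), A = A, W = W),
            class = "block_dictionary")
}

#' @export
print.block_dictionary <- function(x, ...) {
  cat(sprintf("<block_dictionary j=%d, %d x %d atoms (%s)%s>\n",
              x$block_index, nrow(x$atoms), ncol(x$atoms),
              paste(table(x$atom_labels), collapse = "/"),
              if (!is.null(x$W)) ", LC" else ""))
  invisible(x)
}

#' Configuration for dictionary learning and sparse coding
#'
#' @param n_atoms_per_class Atoms learned per class (LS/LC modes); the SLESA
#'   mode ignores it (its dictionaries are the raw training blocks). Default
#'   30, i.e. 60 atoms total, suited to small training sets.
#' @param T_sparsity Sparsity threshold used both in learning and in coding
#'   of test blocks.
#' @param eps Residual stopping tolerance for test-block coding (on
#'   unit-normalized blocks).
#' @param alpha,beta LC-KSVD2 weights of the discriminative sparse-code term
#'   and the classification-error term.
#' @param n_iter KSVD iterations.
#' @param seed RNG seed governing dictionary initialization and atom
#'   replacement.
#' @return List of class `slesa_config`.
#' @export
slesa_config <- function(n_atoms_per_class = 30L, T_sparsity = 5L, eps = 0.01,
                         alpha = 0.04, beta = 0.02, n_iter = 15L, seed = 1L) {
  stopifnot(n_atoms_per_class >= 1, T_sparsity >= 1, eps >= 0,
            alpha >= 0, beta >= 0, n_iter >= 0)
  structure(list(n_atoms_per_class = as.integer(n_atoms_per_class),
                 T_sparsity = as.integer(T_sparsity), eps = eps,
                 alpha = alpha, beta = beta, n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "slesa_config")
}

# Sparse-code every column of Y against D (internal, coefficient rows only;
# compiled OMP core shared with omp()).
omp_code_matrix <- function(D, Y, T_sparsity, eps = 0) {
  .omp_code_matrix_cpp(D, Y, as.integer(T_sparsity), eps)
}

#' One KSVD dictionary-update sweep
#'
#' Updates every atom in turn by the rank-1 SVD of the residual restricted
#' to the samples using that atom, simultaneously updating those samples'
#' coefficients. Atoms used by no sample are replaced by the currently
#' worst-represented training sample (renormalized) with their coefficient
#' row left at zero, so the sweep never increases the Frobenius
#' reconstruction error `||Y - D X||_F`.
#'
#' @param Y d x N training matrix.
#' @param D d x n dictionary (unit-norm atoms).
#' @param X n x N sparse coefficient matrix.
#' @return List with updated `D` and `X`.
#' @export
ksvd_update_sweep <- function(Y, D, X) {
  for (k in seq_len(ncol(D))) {
    users <- which(abs(X[k, ]) > 0)
    if (length(users) == 0) {
      res <- Y - D %*% X
      worst <- which.max(colSums(res^2))
      cand <- Y[, worst]
      if (l2norm(cand) > 0) D[, k] <- cand / l2norm(cand)
      next
    }
    Ek <- Y[, users, drop = FALSE] - D %*% X[, users, drop = FALSE] +
      tcrossprod(D[, k], X[k, users])
    sv <- svd(Ek, nu = 1, nv = 1)
    D[, k] <- sv$u[, 1]
    X[k, users] <- sv$d[1] * sv$v[, 1]
  }
  list(D = D, X = X)
}

# Dictionary-clearing step: atoms that duplicate an earlier atom (absolute
# inner product above coherence_max) or that almost no sample uses are
# replaced by poorly represented training samples. A candidate is accepted
# only if it is itself incoherent with the retained atoms — on highly
# coherent data (where every sample looks like every atom) the original
# atom is kept instead, so clearing never degrades a dictionary that cannot
# be diversified.
dedup_atoms <- function(Y, D, X, coherence_max = 0.99) {
  G <- abs(crossprod(D))
  diag(G) <- 0
  # usage floor scales with the sample count so that small training sets
  # only replace genuinely unused atoms
  min_usage <- max(1L, floor(0.01 * ncol(Y)))
  usage <- rowSums(abs(X) > 1e-12)
  res_order <- order(colSums((Y - D %*% X)^2), decreasing = TRUE)
  available <- rep(TRUE, length(res_order))
  for (k in seq_len(ncol(D))) {
    if (!any(G[seq_len(k - 1L), k] > coherence_max) && usage[k] >= min_usage) next
    for (ci in which(available)) {
      cand <- Y[, res_order[ci]]
      cn <- l2norm(cand)
      if (cn == 0) { available[ci] <- FALSE; next }
      cand <- cand / cn
      if (max(abs(crossprod(D[, -k, drop = FALSE], cand))) > coherence_max) next
      D[, k] <- cand
      X[k, ] <- 0
      available[ci] <- FALSE
      G <- abs(crossprod(D)); diag(G) <- 0
      break
    }
  }
  list(D = D, X = X)
}

# Initial dictionary: n_atoms distinct nonzero training columns, chosen at
# random under the current RNG state; recycled with jitter if Y is too thin.
ksvd_init <- function(Y, n_atoms) {
  nz <- which(colSums(Y^2) > 0)
  if (length(nz) == 0) stop("all-zero training matrix")
  if (length(nz) < n_atoms) {
    warning("fewer nonzero training samples (", length(nz),
            ") than atoms (", n_atoms, "); recycling with jitter")
    idx <- c(nz, sample(nz, n_atoms - length(nz), replace = TRUE))
    D <- Y[, idx, drop = FALSE]
    extra <- seq.int(length(nz) + 1L, n_atoms)
    D[, extra] <- D[, extra] + matrix(stats::rnorm(nrow(Y) * length(extra), sd = 0.01),
                                      nrow(Y))
  } else {
    D <- Y[, sample(nz, n_atoms), drop = FALSE]
  }
  normalize_columns(D)
}

# Alternate coding and atom updates, returning the iterate with the lowest
# reconstruction objective ||Y - D X||_F^2 (greedy re-coding makes the
# alternation non-monotone across iterations, so the best iterate — never
# worse than the initialization — is kept).
ksvd_core <- function(Y, D, T_sparsity, n_iter, coherence_max = 0.99) {
  X <- omp_code_matrix(D, Y, T_sparsity, eps = 0)
  best <- list(D = D, X = X, obj = sum((Y - D %*% X)^2))
  for (it in seq_len(n_iter)) {
    up <- ksvd_update_sweep(Y, D, X)
    up <- dedup_atoms(Y, up$D, up$X, coherence_max = coherence_max)
    D <- up$D
    X <- omp_code_matrix(D, Y, T_sparsity, eps = 0)
    obj <- sum((Y - D %*% X)^2)
    if (obj < best$obj) best <- list(D = D, X = X, obj = obj)
  }
  list(D = best$D, X = best$X)
}

#' KSVD dictionary learning
#'
#' Alternates sparse coding of all training columns (OMP, sparsity `T`)
#' with atom-by-atom rank-1 SVD updates; unused and duplicated atoms are
#' replaced by the worst-represented samples. Deterministic given `seed`.
#'
#' @param Y d x N training matrix (columns are signals).
#' @param n_atoms Number of dictionary atoms.
#' @param T_sparsity Sparsity level used during learning.
#' @param n_iter Number of coding/update iterations.
#' @param seed RNG seed for initialization/replacement.
#' @param coherence_max Clearing threshold: an atom whose absolute inner
#'   product with an earlier atom exceeds this is replaced by a poorly
#'   represented sample. Set it above the mutual coherence expected of the
#'   true atoms: the conservative default 0.99 suits highly coherent
#'   natural-image blocks; for recovery of incoherent (e.g. random)
#'   dictionaries a value just above the expected extreme coherence of
#'   random unit vectors (about `sqrt(2 * log(n_atoms^2) / d)`) clears
#'   blend atoms far more effectively.
#' @return List with `D` (d x n_atoms, unit-norm columns) and `X`
#'   (n_atoms x N codes of `Y` against the final `D`).
#' @export
ksvd <- function(Y, n_atoms, T_sparsity, n_iter = 50L, seed = 1L,
                 coherence_max = 0.99) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 1) stop("need at least one training sample")
  if (all(Y == 0)) stop("all-zero training matrix")
  with_seed(seed, {
    D <- ksvd_init(Y, n_atoms)
    ksvd_core(Y, D, T_sparsity, n_iter, coherence_max = coherence_max)
  })
}

# Split a total atom budget between the two classes; odd totals give the
# extra atom to the benign (-1) class.
split_atom_budget <- function(n_total) {
  c(`-1` = ceiling(n_total / 2), `1` = floor(n_total / 2))
}

#' Label-separated dictionary learning for one block position
#'
#' Runs KSVD independently on the benign and the malignant training blocks
#' (`n_atoms_per_class` atoms each) and concatenates the class dictionaries
#' `[D_benign | D_malignant]` with matching atom labels.
#'
#' @param block A block training matrix entry from
#'   [build_block_training_matrices()] (fields `Y`, `column_labels`,
#'   `block_index`).
#' @param config A [slesa_config()].
#' @return A [block_dictionary()] (no `A`/`W`).
#' @export
ls_learn <- function(block, config) {
  Y <- block$Y; labels <- block$column_labels
  classes <- c(-1, 1)
  if (!all(classes %in% labels)) stop("both classes required for label-separated learning")
  parts <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    ksvd(Y[, labels == cl, drop = FALSE], config$n_atoms_per_class,
         config$T_sparsity, config$n_iter,
         seed = derive_seed(config$seed, block$block_index, ci))$D
  })
  block_dictionary(do.call(cbind, parts),
                   rep(classes, each = config$n_atoms_per_class),
                   block_index = block$block_index)
}

#' Discriminative label matrices for LC-KSVD2
#'
#' `Q` is the n_atoms x N binary matrix with `Q[i, k] = 1` iff atom i and
#' training sample k share a class label; `H` is the 2 x N one-hot class
#' matrix (row order: benign -1, then malignant +1).
#'
#' @param column_labels Class label per training sample.
#' @param atom_labels Class label per atom.
#' @return List with `Q` and `H`.
#' @export
build_label_matrices <- function(column_labels, atom_labels) {
  if (!length(column_labels) || !length(atom_labels)) stop("empty label vectors")
  classes <- sort(unique(c(column_labels, atom_labels)))
  if (!all(column_labels %in% atom_labels)) {
    stop("sample label outside the atom class set")
  }
  Q <- outer(atom_labels, column_labels, "==") * 1
  H <- rbind(as.numeric(column_labels == classes[1]),
             as.numeric(column_labels == classes[length(classes)]))
  rownames(H) <- as.character(classes[c(1, length(classes))])
  list(Q = Q, H = H)
}

#' Label-consistent KSVD2 learning for one block position
#'
#' Minimizes `||Y - DX||^2 + alpha ||Q - AX||^2 + beta ||H - WX||^2`
#' subject to `||x_k||_0 <= T` by running KSVD on the stacked data
#' `[Y; sqrt(alpha) Q; sqrt(beta) H]` with the stacked dictionary
#' `[D; sqrt(alpha) A; sqrt(beta) W]`, then splitting and rescaling so the
#' returned `D` has unit-norm atoms and `A`, `W` are consistent with it.
#' `D` is initialized by a short per-class KSVD (atoms inherit class
#' labels); `A` and `W` by ridge regression of `Q` and `H` on the initial
#' codes. With `alpha = beta = 0` this reduces to plain [ksvd()] on `Y`
#' (same seed, atom labels from the deterministic class split).
#'
#' @inheritParams ls_learn
#' @return A [block_dictionary()] with `A` and `W` populated (unless both
#'   weights are zero).
#' @export
lc_learn <- function(block, config) {
  Y <- block$Y; labels <- block$column_labels
  classes <- c(-1, 1)
  if (!all(classes %in% labels)) stop("both classes required for label-consistent learning")
  alpha <- config$alpha; beta <- config$beta
  n_per <- config$n_atoms_per_class
  atom_labels <- rep(classes, each = n_per)
  seed <- derive_seed(config$seed, block$block_index, 99L)

  if (alpha == 0 && beta == 0) {
    fit <- ksvd(Y, 2L * n_per, config$T_sparsity, config$n_iter, seed = seed)
    return(block_dictionary(fit$D, atom_labels, block_index = block$block_index))
  }

  lm_mats <- build_label_matrices(labels, atom_labels)
  Q <- lm_mats$Q; H <- lm_mats$H
  d <- nrow(Y)

  with_seed(seed, {
    # initialization: short per-class KSVD, then ridge fits for A0, W0
    D0 <- do.call(cbind, lapply(classes, function(cl) {
      ksvd_core(Y[, labels == cl, drop = FALSE],
                ksvd_init(Y[, labels == cl, drop = FALSE], n_per),
                config$T_sparsity, n_iter = min(5L, max(1L, config$n_iter)))$D
    }))
    X0 <- omp_code_matrix(D0, Y, config$T_sparsity)
    G <- tcrossprod(X0) + 1e-4 * diag(nrow(X0))
    A0 <- t(solve(G, tcrossprod(X0, Q)))
    W0 <- t(solve(G, tcrossprod(X0, H)))

    stack <- rbind(Y,
                   if (alpha > 0) sqrt(alpha) * Q,
                   if (beta > 0) sqrt(beta) * H)
    D_stack <- normalize_columns(rbind(D0,
                                       if (alpha > 0) sqrt(alpha) * A0,
                                       if (beta > 0) sqrt(beta) * W0))
    # the stacked residual equals the weighted three-term objective, so
    # these two values track the optimization end to end
    X_stack0 <- omp_code_matrix(D_stack, stack, config$T_sparsity)
    objective_init <- sum((stack - D_stack %*% X_stack0)^2)
    fit <- ksvd_core(stack, D_stack, config$T_sparsity, config$n_iter)
    objective_final <- sum((stack - fit$D %*% fit$X)^2)

    Dp <- fit$D[seq_len(d), , drop = FALSE]
    off <- d
    Ap <- if (alpha > 0) { r <- fit$D[off + seq_len(nrow(Q)), , drop = FALSE]; off <- off + nrow(Q); r / sqrt(alpha) } else NULL
    Wp <- if (beta > 0) fit$D[off + seq_len(nrow(H)), , drop = FALSE] / sqrt(beta) else NULL
    nd <- sqrt(colSums(Dp^2))
    nd[nd == 0] <- 1
    D <- sweep(Dp, 2, nd, "/")
    if (!is.null(Ap)) Ap <- sweep(Ap, 2, nd, "/")
    if (!is.null(Wp)) Wp <- sweep(Wp, 2, nd, "/")
    out <- block_dictionary(D, atom_labels, block_index = block$block_index,
                            A = Ap, W = Wp)
    attr(out, "objective_init") <- objective_init
    attr(out, "objective_final") <- objective_final
    out
  })
}
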