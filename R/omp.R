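# Sparse coding of block vectors over (block) dictionaries.
#
# All coding is done after normalizing the test vector to unit Euclidean
# norm (dictionary atoms are unit-norm by construction); the residual
# tolerance eps is therefore an absolute threshold on the normalized
# residual. Returned coefficients/residuals are rescaled back to the scale
# of the input vector, so D %*% coefficients approximates the raw y.

#' Orthogonal matching pursuit
#'
#' Greedy sparse approximation of `y` over the atoms of `D`: at each step
#' the atom with maximum absolute correlation with the current residual is
#' selected (ties broken toward the lowest atom index), all selected
#' coefficients are re-fit by least squares (minimum-norm solution when the
#' selected atoms are collinear), and the residual is updated. Iteration
#' stops when `T` atoms are selected, the normalized residual drops to
#' `eps`, or the residual becomes orthogonal to every atom.
#'
#' @param D Dictionary: d x n matrix of unit-norm atoms, or a
#'   `block_dictionary`.
#' @param y Signal vector of length d. A zero vector yields the all-zero
#'   code with zero residual.
#' @param T_sparsity Maximum number of selected atoms (>= 1).
#' @param eps Residual tolerance on the unit-normalized signal (>= 0).
#' @return An object of class `sparse_code`: `coefficients` (length n, zero
#'   off-support), `support` (selected atom indices in selection order),
#'   `residual_norm`, and — when `D` carries atom labels — `per_class_l1`
#'   and `per_class_residual`, named by class.
#' @export
omp <- function(D, y, T_sparsity, eps = 0) {
  atom_labels <- NULL
  if (inherits(D, "block_dictionary")) { atom_labels <- D$atom_labels; D <- D$atoms }
  D <- as.matrix(D)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(D)) stop("NaN/NA in OMP input")
  if (length(y) != nrow(D)) stop("signal length ", length(y), " != atom length ", nrow(D))
  T_sparsity <- as.integer(T_sparsity)
  if (T_sparsity < 1) stop("T_sparsity must be >= 1")
  if (eps < 0) stop("eps must be >= 0")

  x <- as.vector(.omp_code_cpp(D, y, T_sparsity, eps))
  support <- which(x != 0)
  new_sparse_code(x, support, l2norm(y - D %*% x), D, y, atom_labels)
}

new_sparse_code <- function(x, support, residual_norm, D, y, atom_labels) {
  code <- list(coefficients = x, support = support,
               residual_norm = residual_norm)
  if (!is.null(atom_labels)) {
    classes <- sort(unique(atom_labels))
    code$per_class_l1 <- vapply(classes, function(cl) sum(abs(x[atom_labels == cl])), numeric(1))
    code$per_class_residual <- vapply(classes, function(cl) {
      l2norm(D %*% class_restrict(x, atom_labels, cl) - y)
    }, numeric(1))
    names(code$per_class_l1) <- names(code$per_class_residual) <- classes
    code$atom_labels <- atom_labels
  }
  structure(code, class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code |support|=%d residual=%.4g>\n",
              length(x$support), x$residual_norm))
  invisible(x)
}

#' Zero out coefficients outside one class
#'
#' The class-indicator operator of sparse representation classification:
#' returns a copy of the coefficient vector with every coefficient whose
#' atom label differs from `class` set to zero.
#'
#' @param x Coefficient vector (or a `sparse_code`).
#' @param atom_labels Class label per atom.
#' @param class Class to keep.
#' @return Numeric vector of the same length as `x`.
#' @export
class_restrict <- function(x, atom_labels, class) {
  if (inherits(x, "sparse_code")) x <- x$coefficients
  if (!class %in% atom_labels) stop("class ", class, " absent from atom labels")
  out <- as.numeric(x)
  out[atom_labels != class] <- 0
  out
}

#' Class-restricted reconstruction residual
#'
#' Euclidean norm of `D %*% class_restrict(x, class) - y`: how well the
#' atoms of one class alone reconstruct the signal.
#'
#' @param D Dictionary matrix or `block_dictionary`.
#' @param x Coefficient vector or `sparse_code`.
#' @param y Signal vector.
#' @param atom_labels Class label per atom (taken from `D` if it is a
#'   `block_dictionary`).
#' @param class Class whose atoms are kept.
#' @return Nonnegative scalar.
#' @export
class_residual <- function(D, x, y, class, atom_labels = NULL) {
  if (inherits(D, "block_dictionary")) { atom_labels <- D$atom_labels; D <- D$atoms }
  if (is.null(atom_labels)) stop("atom_labels required")
  if (nrow(D) != length(y)) stop("dimension mismatch between D and y")
  l2norm(D %*% class_restrict(x, atom_labels, class) - y)
}

#' Exhaustive best-subset sparse coding (test oracle)
#'
#' Enumerates every support of size <= `T_sparsity`, fits each by least
#' squares, and returns the minimum-residual code. Combinatorial: intended
#' only as an independent reference on tiny problems.
#'
#' @inheritParams omp
#' @return A `sparse_code` (support sorted; no class masses attached).
#' @export
exhaustive_sparse_code <- function(D, y, T_sparsity) {
  if (inherits(D, "block_dictionary")) D <- D$atoms
  D <- as.matrix(D); y <- as.numeric(y)
  n <- ncol(D)
  if (n > 12 || T_sparsity > 2) stop("oracle bound exceeded (n_atoms <= 12, T <= 2)")
  best <- list(support = integer(0), coef = numeric(0), res = l2norm(y))
  for (k in seq_len(T_sparsity)) {
    combos <- utils::combn(n, k)
    for (i in seq_len(ncol(combos))) {
      s <- combos[, i]
      cf <- lstsq_minnorm(D[, s, drop = FALSE], y)
      res <- l2norm(y - D[, s, drop = FALSE] %*% cf)
      if (res < best$res - 1e-15) best <- list(support = s, coef = cf, res = res)
    }
  }
  x <- rep(0, n)
  x[best$support] <- best$coef
  new_sparse_code(x, best$support, best$res, D, y, NULL)
}
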