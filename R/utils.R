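# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic entry points go
# through this so that user-level RNG state is never disturbed.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and integer tags; stays below 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(as.numeric(seed), as.numeric(c(...)))
  s <- 0
  for (t in tags) s <- (s * 69069 + t + 1) %% 2147483647
  as.integer(s)
}

l2norm <- function(x) sqrt(sum(x^2))

# Column-normalize a matrix to unit Euclidean norm; zero columns untouched.
normalize_columns <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nz <- nrm > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
  M
}

# Minimum-norm least-squares solution of A x = b via SVD with a rank
# tolerance; exactly collinear columns thus receive the minimum-norm split.
lstsq_minnorm <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(rep(0, ncol(A)))
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  as.vector(sv$v %*% (d_inv * crossprod(sv$u, b)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
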