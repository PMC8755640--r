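test_that("ksvd on replicated data reduces to the rank-1 SVD solution", {
  v <- c(3, 0, 4)
  Y <- matrix(v, 3, 5)
  fit <- ksvd(Y, n_atoms = 1, T_sparsity = 1, n_iter = 3, seed = 1)
  expect_equal(abs(sum(fit$D[, 1] * v / 5)), 1, tolerance = 1e-12)  # atom = +-v/||v||
  expect_equal(fit$D %*% fit$X, Y, tolerance = 1e-12)
  expect_equal(abs(fit$X[1, ]), rep(5, 5), tolerance = 1e-12)
})

test_that("a dictionary-update sweep never increases the reconstruction error", {
  for (seed in 1:20) {
    p <- recovery_problem(d = 10, n_atoms = 14, n_samples = 60, T0 = 2,
                          noise_sd = 0.05, seed = seed)
    D <- random_dictionary(10, 14, seed = seed + 500)
    X <- slesa:::omp_code_matrix(D, p$Y, 2)
    before <- sum((p$Y - D %*% X)^2)
    up <- ksvd_update_sweep(p$Y, D, X)
    after <- sum((p$Y - up$D %*% up$X)^2)
    expect_lte(after, before + 1e-10)
  }
})

test_that("ksvd learns unit-norm, non-duplicated atoms and is reproducible", {
  p <- recovery_problem(d = 12, n_atoms = 16, n_samples = 120, T0 = 2, seed = 4)
  fit1 <- ksvd(p$Y, 16, 2, n_iter = 10, seed = 42)
  fit2 <- ksvd(p$Y, 16, 2, n_iter = 10, seed = 42)
  expect_identical(fit1$D, fit2$D)            # bit-for-bit reproducible
  expect_equal(sqrt(colSums(fit1$D^2)), rep(1, 16), tolerance = 1e-8)
  G <- abs(crossprod(fit1$D))
  diag(G) <- 0
  expect_lt(max(G), 1 - 1e-6)
})

test_that("ksvd recovers most atoms of a planted incoherent dictionary", {
  # scaled-down recovery run; the full protocol lives in the acceptance suite
  p <- recovery_problem(d = 16, n_atoms = 24, n_samples = 400, T0 = 3,
                        noise_sd = 0.01, seed = 2)
  fit <- ksvd(p$Y, 24, 3, n_iter = 30, seed = 2, coherence_max = 0.85)
  expect_gte(atom_recovery_rate(fit$D, p$Dstar), 0.7)
})

test_that("ksvd rejects degenerate input", {
  expect_error(ksvd(matrix(0, 4, 6), 2, 1), "all-zero")
  expect_warning(ksvd(matrix(rnorm(8), 4, 2), 4, 1, n_iter = 1, seed = 1),
                 "fewer")
})

test_that("label matrices Q and H encode shared class membership", {
  lm <- build_label_matrices(c("A", "B"), c("A", "B"))
  expect_equal(lm$Q, diag(2) * 1)

  lm2 <- build_label_matrices("B", c("A", "A", "B", "B"))
  expect_equal(lm2$Q, matrix(c(0, 0, 1, 1), 4, 1))

  lm3 <- build_label_matrices(c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(lm3$H), cbind(c(1, 0), c(0, 1), c(0, 1)))

  expect_error(build_label_matrices(c("A", "C"), c("A", "B")), "class set")
  expect_error(build_label_matrices(character(0), "A"), "empty")
})

test_that("label-separated learning yields class dictionaries that favor their own class", {
  rois <- small_roi_set(n_per_class = 10, seed = 21)
  blocks <- build_block_training_matrices(rois[1:16], c(8, 8))
  cfg <- slesa_config(n_atoms_per_class = 8, T_sparsity = 3, n_iter = 10, seed = 3)
  dict <- ls_learn(blocks[[5]], cfg)

  expect_s3_class(dict, "block_dictionary")
  expect_equal(table(dict$atom_labels), table(c(rep(-1, 8), rep(1, 8))))
  expect_equal(sqrt(colSums(dict$atoms^2)), rep(1, 16), tolerance = 1e-8)
  expect_null(dict$W)

  # held-out blocks: own-class mean reconstruction residual < cross-class
  held <- build_block_training_matrices(rois[17:20], c(8, 8),
                                        require_both_classes = FALSE)[[5]]
  resid <- function(y, cl) {
    sub <- dict$atoms[, dict$atom_labels == cl, drop = FALSE]
    x <- slesa:::omp_code_matrix(sub, cbind(y), cfg$T_sparsity)
    slesa:::l2norm(y - sub %*% x)
  }
  own <- cross <- numeric(0)
  for (i in seq_along(held$column_labels)) {
    y <- held$Y[, i]; cl <- held$column_labels[i]
    own <- c(own, resid(y, cl)); cross <- c(cross, resid(y, -cl))
  }
  expect_lt(mean(own), mean(cross))

  # reproducibility: identical inputs and seeds give identical dictionaries
  expect_identical(dict$atoms, ls_learn(blocks[[5]], cfg)$atoms)
})

test_that("ls_learn requires both classes", {
  rois <- small_roi_set(n_per_class = 4, seed = 2)
  b <- build_block_training_matrices(rois, c(8, 8))[[1]]
  b$column_labels[] <- 1
  expect_error(ls_learn(b, slesa_config()), "both classes")
})

test_that("label-consistent learning reduces to ksvd at zero weights", {
  rois <- small_roi_set(n_per_class = 6, seed = 13)
  block <- build_block_training_matrices(rois, c(8, 8))[[3]]
  cfg <- slesa_config(n_atoms_per_class = 5, T_sparsity = 3, alpha = 0,
                      beta = 0, n_iter = 5, seed = 17)
  lc <- lc_learn(block, cfg)
  plain <- ksvd(block$Y, 10, 3, n_iter = 5,
                seed = slesa:::derive_seed(17, block$block_index, 99L))
  expect_identical(lc$atoms, plain$D)
  expect_null(lc$W)
})

test_that("label-consistent learning produces discriminative codes and a usable classifier", {
  rois <- small_roi_set(n_per_class = 10, seed = 31)
  block <- build_block_training_matrices(rois, c(8, 8))[[7]]
  cfg <- slesa_config(n_atoms_per_class = 8, T_sparsity = 3,
                      alpha = 0.04, beta = 0.02, n_iter = 10, seed = 5)
  dict <- lc_learn(block, cfg)
  expect_equal(sqrt(colSums(dict$atoms^2)), rep(1, 16), tolerance = 1e-8)
  expect_equal(dim(dict$A), c(16, 16))
  expect_equal(dim(dict$W), c(2, 16))

  # the three-term objective did not get worse during learning
  expect_lte(attr(dict, "objective_final"), attr(dict, "objective_init") + 1e-8)

  X <- slesa:::omp_code_matrix(dict$atoms, block$Y, cfg$T_sparsity)
  labs <- block$column_labels

  # within-class sparse codes correlate more than between-class codes
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  same <- outer(labs, labs, "==") & upper.tri(C)
  diff_ <- outer(labs, labs, "!=") & upper.tri(C)
  expect_gt(mean(C[same]), mean(C[diff_]))

  # W applied to training codes at least matches a label-agnostic
  # KSVD + nearest-class-residual baseline
  pred_w <- ifelse(apply(dict$W %*% X, 2, which.max) == 2, 1, -1)
  acc_w <- mean(pred_w == labs)

  base <- ksvd(block$Y, 16, 3, n_iter = 10, seed = 5)
  base_labels <- c(rep(-1, 8), rep(1, 8))  # arbitrary split: label-agnostic
  Xb <- slesa:::omp_code_matrix(base$D, block$Y, 3)
  pred_b <- vapply(seq_along(labs), function(i) {
    rb <- slesa:::l2norm(block$Y[, i] - base$D %*% class_restrict(Xb[, i], base_labels, -1))
    rm <- slesa:::l2norm(block$Y[, i] - base$D %*% class_restrict(Xb[, i], base_labels, 1))
    if (rm < rb) 1 else -1
  }, numeric(1))
  expect_gte(acc_w, mean(pred_b == labs))
})
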