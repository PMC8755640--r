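# Shared fixtures, all generated in code under fixed seeds.

# Random dictionary with unit-norm atoms.
random_dictionary <- function(d, n, seed = 1) {
  slesa:::with_seed(seed, {
    D <- matrix(stats::rnorm(d * n), d, n)
  })
  slesa:::normalize_columns(D)
}

# Standard dictionary-recovery problem: ground-truth unit atoms, samples
# that are exact T0-sparse combinations plus Gaussian noise.
recovery_problem <- function(d = 16, n_atoms = 32, n_samples = 600,
                             T0 = 3, noise_sd = 0.01, seed = 1) {
  slesa:::with_seed(seed, {
    Dstar <- slesa:::normalize_columns(matrix(stats::rnorm(d * n_atoms), d, n_atoms))
    X <- matrix(0, n_atoms, n_samples)
    for (i in seq_len(n_samples)) X[sample(n_atoms, T0), i] <- stats::rnorm(T0)
    Y <- Dstar %*% X + matrix(stats::rnorm(d * n_samples, sd = noise_sd), d, n_samples)
    list(Dstar = Dstar, X = X, Y = Y)
  })
}

# Greedy one-to-one matching of learned to true atoms by |inner product|;
# returns the fraction matched above `thresh`.
atom_recovery_rate <- function(D_learned, D_true, thresh = 0.99) {
  G <- abs(crossprod(D_learned, D_true))
  matched <- 0
  for (k in seq_len(ncol(D_true))) {
    i <- which(G == max(G), arr.ind = TRUE)[1, ]
    if (G[i[1], i[2]] > thresh) matched <- matched + 1
    G[i[1], ] <- -1
    G[, i[2]] <- -1
  }
  matched / ncol(D_true)
}

# Small, quickly separable two-class ROI set (coarse vs fine texture).
small_roi_set <- function(n_per_class = 8, side = 32, noise = 0.03, seed = 7) {
  cfg <- synthetic_config(side_px = side, noise_sigma = noise,
                          n_benign = n_per_class, n_malignant = n_per_class,
                          seed = seed)
  generate_dataset(cfg)
}

# Hand-built sparse_code stub with prescribed class masses/residuals.
fake_code <- function(l1_benign, l1_malignant, res_benign = 1, res_malignant = 1) {
  structure(list(
    coefficients = numeric(0), support = integer(0), residual_norm = 0,
    per_class_l1 = c(`-1` = l1_benign, `1` = l1_malignant),
    per_class_residual = c(`-1` = res_benign, `1` = res_malignant)
  ), class = "sparse_code")
}

# Brute-force Mann-Whitney concordance AUC (ties counted 1/2).
concordance_auc <- function(labels, scores) {
  xs <- scores[labels == 1]
  ys <- scores[labels == -1]
  total <- 0
  for (x in xs) total <- total + sum(x > ys) + 0.5 * sum(x == ys)
  total / (length(xs) * length(ys))
}
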