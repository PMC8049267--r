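# Shared fixtures, all generated in code at test time.

table1_counts <- c(36L, 38L, 31L, 26L, 38L, 40L)

# tiny fast dataset: 2 specimens per class, no artifacts
tiny_spec <- function(seed = 1L, ...) {
  synth_spec(n_per_class = rep(2L, 6), seed = seed, ...)
}

# two well-separated Gaussian blobs differing only in feature 1 of 5
blob_fixture <- function(n_per_class = 20, gap = 6, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * 5), 2 * n_per_class, 5)
  y <- rep(0:1, each = n_per_class)
  X[, 1] <- X[, 1] + gap * y
  list(X = X, y = y)
}

# latent-linear data: D-dimensional observations from a 2-D latent Gaussian
linear_latent_fixture <- function(N = 60, D = 20, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  Xtrue <- matrix(rnorm(N * 2), N, 2)
  W <- matrix(rnorm(2 * D), 2, D)
  list(Y = Xtrue %*% W + matrix(rnorm(N * D, 0, noise_sd), N, D),
       X = Xtrue, W = W)
}

# largest principal angles (degrees) between the column spaces of A and B
principal_angles <- function(A, B) {
  sv <- svd(crossprod(qr.Q(qr(A)), qr.Q(qr(B))))$d
  acos(pmin(1, sv)) * 180 / pi
}
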