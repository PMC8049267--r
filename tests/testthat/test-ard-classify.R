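test_that("GPC separates Gaussian blobs and ranks the informative feature", {
  bf <- blob_fixture(n_per_class = 15, gap = 6, seed = 1)
  holdout <- blob_fixture(n_per_class = 10, gap = 6, seed = 2)
  fit <- fit_gpc(bf$X, bf$y, seed = 1)
  pr <- predict(fit, holdout$X)
  expect_equal(accuracy(pr$predicted, holdout$y), 100)
  expect_identical(unname(which.max(fit$ard_profile$alpha)), 1L)
  expect_equal(rowSums(pr$posterior), rep(1, 20), tolerance = 1e-8)
  expect_true(all(pr$posterior >= 0 & pr$posterior <= 1))
})

test_that("GPC on shuffled labels stays near the majority rate", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(0:1, each = 30)   # balanced; majority rate 50%
  yshuf <- sample(y)
  fit <- fit_gpc(X, yshuf, seed = 3)
  pr <- predict(fit, X)
  # mean posterior per class approximately the class frequency
  expect_equal(unname(colMeans(pr$posterior)), c(0.5, 0.5), tolerance = 0.05)
})

test_that("GPC errors when a class is missing from the training fold", {
  bf <- blob_fixture(seed = 4)
  expect_error(fit_gpc(bf$X, bf$y, levels = 0:2), "absent.*2")
  expect_error(fit_gpc(matrix(1:10, 5, 2), rep(0, 5)), "two classes")
  expect_error(fit_gpc(matrix(c(1, NA, 3, 4), 2, 2), 0:1), "finite")
})

test_that("GPC marginal-likelihood gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3)
  t01 <- as.numeric(runif(20) < 0.5)
  D2 <- morphsal:::sq_diff_mat(X)
  th <- rnorm(4, 0, 0.3)
  ob <- morphsal:::gpc_nlml_t(th, D2, t01)
  ng <- pracma::grad(function(p) morphsal:::gpc_nlml_t(p, D2, t01)$value, th)
  expect_equal(ob$grad, ng, tolerance = 1e-6)
})

test_that("HMC-MLP separates blobs and attenuates irrelevant inputs", {
  bf <- blob_fixture(n_per_class = 15, gap = 6, seed = 6)
  holdout <- blob_fixture(n_per_class = 10, gap = 6, seed = 7)
  fit <- fit_hmc_mlp(bf$X, bf$y, hidden = 8, n_samples = 300, seed = 1)
  pr <- predict(fit, holdout$X)
  expect_equal(accuracy(pr$predicted, holdout$y), 100)
  comb <- fit$ard_profile$combined
  expect_identical(unname(which.max(comb)), 1L)
  expect_equal(rowSums(pr$posterior), rep(1, 20), tolerance = 1e-8)
  expect_gt(fit$acceptance, 0.3)
})

test_that("a zero-variance input lands in the lowest relevance quartile", {
  # every live feature is necessary (two binary factors spanning 4 classes
  # plus their interaction); the dead column must fall below all of them
  set.seed(8)
  n <- 48
  bit1 <- rep(0:1, each = n / 2)
  bit2 <- rep(rep(0:1, each = n / 4), 2)
  y <- 2 * bit1 + bit2
  X <- cbind(6 * bit1 + rnorm(n), 6 * bit2 + rnorm(n),
             3 * bit1 + 3 * bit2 + rnorm(n), dead = 0)
  fit <- fit_hmc_mlp(X, y, hidden = 8, n_samples = 400, seed = 1)
  comb <- fit$ard_profile$combined
  expect_identical(unname(which.min(comb)), 4L)
  expect_lte(comb[4], stats::quantile(comb, 0.25) + 1e-9)
})

test_that("HMC-MLP accepts one-hot targets and validates them", {
  bf <- blob_fixture(n_per_class = 10, seed = 9)
  Yoh <- cbind(1 - bf$y, bf$y)
  fit <- fit_hmc_mlp(bf$X, Yoh, hidden = 4, n_samples = 100, seed = 3)
  expect_identical(fit$n_class, 2L)
  bad <- Yoh; bad[1, ] <- c(1, 1)
  expect_error(fit_hmc_mlp(bf$X, bad, hidden = 4), "one-hot")
  expect_error(fit_hmc_mlp(bf$X, bf$y, hidden = 0), "hidden")
})

test_that("MLP relevance combination follows the summed-squares rule", {
  expect_equal(combine_mlp_relevance(3, 4), 5)
  s1 <- c(1.2, 0, 2)
  expect_identical(combine_mlp_relevance(s1, rep(0, 3)), s1)
  set.seed(10)
  a <- runif(8); b <- runif(8)
  expect_equal(combine_mlp_relevance(a, b), sqrt(a^2 + b^2))
  expect_error(combine_mlp_relevance(c(-1, 2), c(1, 2)), "nonnegative")
  expect_error(combine_mlp_relevance(1:3, 1:2), "equal length")
})

test_that("combined GPC length scale matches its least-squares definition", {
  # closed form on the worked pattern
  expect_equal(combine_gpc_lengthscales(c(1, 3), rbind(c(1, 0), c(0, 1))), 2)
  # identity cases
  expect_equal(combine_gpc_lengthscales(c(4, 4), matrix(rnorm(10), 5, 2)), 4)
  expect_equal(combine_gpc_lengthscales(7, matrix(rnorm(5), 5, 1)), 7)
  expect_error(combine_gpc_lengthscales(c(1, 2), matrix(0, 3, 2)), "zero")
  # oracle: golden-section / grid minimization of the quadratic objective
  set.seed(11)
  for (i in 1:100) {
    j <- sample(1:4, 1)
    alphas <- runif(j + 1, 0, 5)
    eta <- matrix(rnorm(6 * (j + 1)), 6, j + 1)
    # oracle: QR least-squares solve of w ~ a q
    q <- rowSums(eta^2)
    w <- as.vector(eta^2 %*% alphas)
    opt <- as.vector(qr.solve(cbind(q), w))
    expect_equal(combine_gpc_lengthscales(alphas, eta), opt,
                 tolerance = 1e-8)
  }
})

test_that("landmark aggregation respects the x/y column convention", {
  # GPC: both coordinates of a landmark share alpha = a  ->  relevance a
  alpha <- rep(c(2, 5), times = c(2, 2))        # two landmarks
  samples <- matrix(rnorm(40), 10, 4)
  rel <- landmark_relevance(alpha, "gpc", samples,
                            acronyms = c("L1", "L2"))
  expect_equal(unname(rel), c(2, 5))
  # MLP: sigma pairs (3, 4) per coordinate -> sqrt(9+16+9+16) per landmark
  prof <- list(sigma1 = rep(3, 4), sigma2 = rep(4, 4))
  relm <- landmark_relevance(prof, "mlp", acronyms = c("L1", "L2"))
  expect_equal(unname(relm), rep(sqrt(50), 2))
  # permuting landmark order permutes outputs identically
  alpha2 <- alpha[c(3, 4, 1, 2)]
  rel2 <- landmark_relevance(alpha2, "gpc", samples[, c(3, 4, 1, 2)],
                             acronyms = c("L2", "L1"))
  expect_equal(unname(rel2), c(5, 2))
  expect_error(landmark_relevance(c(1, 2, 3), "gpc", samples), "even")
})
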