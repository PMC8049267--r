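test_that("bound gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  set.seed(42)
  N <- 8; L <- 2; M <- 3; D <- 5
  Y <- matrix(rnorm(N * D), N, D)
  YYt <- tcrossprod(Y); trYY <- sum(diag(YYt))
  par0 <- c(rnorm(N * L), log(runif(N * L, 0.2, 1)), rnorm(M * L),
            log(runif(L, 0.5, 2)), log(1.3), log(2.1))
  ob <- morphsal:::gplvm_obj(par0, N, L, M, D, YYt, trYY)
  ng <- pracma::grad(function(p)
    morphsal:::gplvm_obj(p, N, L, M, D, YYt, trYY)$value, par0,
    heps = 1e-6)
  expect_lt(max(abs(ng - ob$grad) / pmax(1, abs(ng))), 1e-5)
})

test_that("ARD recovers the true latent dimensionality of linear data", {
  lf <- linear_latent_fixture(N = 60, D = 20, noise_sd = 0.05, seed = 1)
  fit <- fit_gplvm(lf$Y, latent_dim = 4, n_inducing = 15,
                   iterations = 500, seed = 2)
  a <- fit$inv_length_scales
  # exactly 2 dimensions carry the ARD weight; the others are attenuated
  expect_gte(sum(sort(a, decreasing = TRUE)[1:2]) / sum(a), 0.95)
  # the recovered top-2 subspace aligns with the generating one
  rk <- rank_dimensions(fit)[1:2]
  ang <- principal_angles(fit$means[, rk], lf$X)
  expect_lt(min(ang), 5)
  expect_lt(max(ang), 20)
})

test_that("refitting with the same seed reproduces the bound exactly", {
  lf <- linear_latent_fixture(N = 30, D = 10, seed = 3)
  f1 <- fit_gplvm(lf$Y, 3, 8, iterations = 100, seed = 5)
  f2 <- fit_gplvm(lf$Y, 3, 8, iterations = 100, seed = 5)
  expect_identical(f1$bound, f2$bound)
  expect_identical(f1$means, f2$means)
})

test_that("optimization never worsens the initial bound", {
  lf <- linear_latent_fixture(N = 30, D = 10, seed = 4)
  fit <- fit_gplvm(lf$Y, 3, 8, iterations = 150, seed = 1)
  expect_gte(fit$bound, fit$bound_init)
})

test_that("input contracts are enforced", {
  lf <- linear_latent_fixture(N = 10, D = 5, seed = 5)
  expect_error(fit_gplvm(lf$Y, 2, 20), "n_inducing")
  expect_error(fit_gplvm(lf$Y, 2, 1), "n_inducing >= 2")
  Yb <- lf$Y; Yb[1, 1] <- NA
  expect_error(fit_gplvm(Yb, 2, 4), "finite")
})

test_that("model selection picks the plateau and the best latent dimension", {
  lf <- linear_latent_fixture(N = 40, D = 12, noise_sd = 0.2, seed = 6)
  sel <- select_model(lf$Y, latent_dims = c(2, 4),
                      inducing_counts = c(5, 10, 15),
                      iterations = 150, seed = 1)
  expect_true(sel$n_inducing %in% c(5, 10, 15))
  expect_true(sel$latent_dim %in% c(2, 4))
  expect_length(sel$bound_by_inducing, 3)
  expect_length(sel$bound_by_latent, 2)
  expect_warning(select_model(lf$Y, 2, 5, iterations = 50), "single")
})

test_that("dimension ranking sorts by ARD weight with index tie-break", {
  fake <- structure(list(inv_length_scales = c(0.1, 5, 2)),
                    class = "gplvm_fit")
  expect_identical(rank_dimensions(fake), c(2L, 3L, 1L))
  fake2 <- structure(list(inv_length_scales = rep(1, 4)),
                     class = "gplvm_fit")
  expect_identical(rank_dimensions(fake2), 1:4)
  set.seed(7)
  a <- runif(10)
  fake3 <- structure(list(inv_length_scales = a), class = "gplvm_fit")
  expect_identical(rank_dimensions(fake3), order(a, decreasing = TRUE))
})

test_that("projection localizes saliency where a dimension acts", {
  # dimension 1 of the latent controls only a pixel block; the saliency of
  # the corresponding fitted dimension must concentrate there
  set.seed(8)
  N <- 50; side <- 8; D <- side * side
  x1 <- 2 * rnorm(N); x2 <- rnorm(N)   # scale-separated factors
  W1 <- matrix(0, side, side); W1[2:4, 2:4] <- 1        # block for dim 1
  W2 <- matrix(0, side, side); W2[5:7, 5:7] <- 1        # block for dim 2
  Y <- outer(x1, as.vector(W1)) + outer(x2, as.vector(W2)) +
    matrix(rnorm(N * D, 0, 0.05), N, D)
  attr(Y, "img_dim") <- c(side, side)
  fit <- fit_gplvm(Y, latent_dim = 3, n_inducing = 12,
                   iterations = 400, seed = 3)
  rk <- rank_dimensions(fit)
  sal1 <- project_dimension(fit, rk[1])$values
  sal2 <- project_dimension(fit, rk[2])$values
  expect_true(all(sal1 >= 0) && all(dim(sal1) == c(side, side)))
  blocks <- list(morphsal:::dilate_mask(W1 > 0, 1L),
                 morphsal:::dilate_mask(W2 > 0, 1L))
  # each of the two leading dimensions claims one block with >= 90% of its
  # saliency mass
  share <- function(sal, blk) sum(sal[blk]) / sum(sal)
  best1 <- max(share(sal1, blocks[[1]]), share(sal1, blocks[[2]]))
  best2 <- max(share(sal2, blocks[[1]]), share(sal2, blocks[[2]]))
  expect_gte(best1, 0.9)
  expect_gte(best2, 0.9)
  # an attenuated dimension projects to near-zero saliency
  sal3 <- project_dimension(fit, rk[3])$values
  expect_lt(max(sal3), 0.05 * max(sal1))
  expect_error(project_dimension(fit, 9), "out of range")
})

test_that("projection in the linear limit is proportional to the loading", {
  set.seed(9)
  N <- 40; D <- 15
  x <- rnorm(N)
  w <- rnorm(D)
  Y <- outer(x, w) + matrix(rnorm(N * D, 0, 0.02), N, D)
  attr(Y, "img_dim") <- c(3, 5)
  fit <- fit_gplvm(Y, latent_dim = 2, n_inducing = 10,
                   iterations = 300, seed = 1)
  sal <- as.vector(project_dimension(fit, rank_dimensions(fit)[1])$values)
  cosine <- sum(sal * abs(w)) / sqrt(sum(sal^2) * sum(w^2))
  expect_gt(cosine, 0.95)
})

test_that("screening flags nothing when the foreground covers everything", {
  lf <- linear_latent_fixture(N = 30, D = 16, seed = 10)
  Y <- lf$Y
  attr(Y, "img_dim") <- c(4, 4)
  fit <- fit_gplvm(Y, 2, 8, iterations = 100, seed = 2)
  scr <- screen_dimensions(fit, matrix(TRUE, 4, 4), top_k = 2,
                           n_resamples = 100, seed = 3)
  expect_false(any(scr$report$artifact_flag))
  expect_identical(sort(scr$selected), sort(rank_dimensions(fit)[1:2]))
  expect_error(screen_dimensions(fit, matrix(TRUE, 4, 4), top_k = 5),
               "top_k")
})

test_that("latent representations serialize to CSV", {
  lf <- linear_latent_fixture(N = 20, D = 8, seed = 11)
  fit <- fit_gplvm(lf$Y, 2, 6, iterations = 50, seed = 1)
  td <- withr::local_tempdir()
  write_latent(fit, td)
  mu <- utils::read.csv(file.path(td, "means.csv"))
  expect_identical(dim(mu), c(20L, 2L))
  pr <- utils::read.csv(file.path(td, "params.csv"))
  expect_equal(pr$value[pr$name == "bound"], fit$bound)
})
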