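test_that("cross-test plans partition specimens into near-equal strata", {
  labels <- rep(0:5, times = table1_counts)   # N = 209
  plan <- make_plan(labels, 10, 10, seed = 1)
  for (r in 1:10) {
    sizes <- as.vector(table(plan$folds[, r]))
    # 209 = 9 x 21 + 1 x 20
    expect_identical(sort(sizes), c(20L, rep(21L, 9)))
    # every specimen tested exactly once per reshuffle
    expect_identical(sum(sizes), 209L)
    # stratification: every class in every training split
    for (f in 1:10)
      expect_true(all(0:5 %in% labels[plan$folds[, r] != f]))
  }
  expect_identical(make_plan(labels, 10, 10, seed = 1)$folds, plan$folds)
  expect_false(identical(plan$folds[, 1], plan$folds[, 2]))
  expect_error(make_plan(0:4, n_folds = 10), "more folds")
})

test_that("accuracy is the percentage of agreeing labels", {
  expect_equal(accuracy(c(1, 1, 0), c(1, 1, 0)), 100)
  expect_equal(accuracy(c(1, 1, 0), c(0, 0, 1)), 0)
  labels <- rep(0:5, times = table1_counts)
  base <- predict(baseline_majority(labels), NULL, n = length(labels))
  expect_equal(accuracy(base$predicted, labels), 100 * 40 / 209)
  expect_error(accuracy(integer(0), integer(0)), "nonempty")
})

test_that("mutual information is zero for the marginal predictor and maximal for a perfect one", {
  labels <- rep(0:5, times = table1_counts)
  base <- predict(baseline_majority(labels), NULL, n = length(labels))
  expect_identical(mutual_information(base$posterior, labels), 0)
  # perfect one-hot predictions on uniform classes reach channel capacity
  yu <- rep(0:5, each = 10)
  P <- outer(yu, 0:5, "==") * 1
  colnames(P) <- 0:5
  expect_equal(mutual_information(P, yu), log2(6))
  # independent double-sum oracle on a random posterior table
  set.seed(2)
  Pr <- matrix(rexp(60 * 6), 60, 6)
  Pr <- Pr / rowSums(Pr)
  colnames(Pr) <- 0:5
  yr <- sample(0:5, 60, replace = TRUE)
  marg <- sapply(0:5, function(l) mean(yr == l))
  acc <- 0
  for (n in 1:60) for (c in 1:6)
    if (Pr[n, c] > 0 && marg[c] > 0)
      acc <- acc + Pr[n, c] * log2(Pr[n, c] / marg[c])
  expect_equal(mutual_information(Pr, yr), unname(acc / 60))
  expect_true(mutual_information(Pr, yr) >= 0)
  expect_true(mutual_information(Pr, yr) <= log2(6))
})

test_that("exact McNemar matches binomial enumeration", {
  t6 <- rep(0, 6)
  a <- rep(0, 6)                 # all correct
  b6 <- rep(1, 6)                # all wrong
  mc <- mcnemar(a, b6, t6)
  expect_identical(c(mc$n_a, mc$n_b), c(6L, 0L))
  expect_equal(mc$p, 0.03125)    # 2 * C(6,0) / 2^6
  b5 <- c(0, rep(1, 5)); a5 <- c(1, rep(0, 5))
  mc2 <- mcnemar(a5, b5, t6)     # n_a = 5, n_b = 1
  expect_equal(mc2$p, 0.21875)   # 2 * (1 + 6) / 2^6
  # identical predictions: no discordance, p = 1 with warning
  expect_warning(mc3 <- mcnemar(a, a, t6), "no discordant")
  expect_identical(c(mc3$n_a, mc3$n_b, mc3$p), c(0L, 0L, 1))
  # full enumeration oracle for all n_a + n_b <= 12
  for (na in 0:12) for (nb in 0:(12 - na)) {
    if (na + nb == 0) next
    predA <- c(rep(0, na), rep(1, nb), 0, 0)
    predB <- c(rep(1, na), rep(0, nb), 0, 0)
    truth <- rep(0, na + nb + 2)
    m <- na + nb
    k <- min(na, nb)
    # exhaustive: P(X <= k) by enumerating all 2^m equally likely outcomes
    cnt <- sum(vapply(0:(2^m - 1), function(code) {
      sum(as.integer(intToBits(code))[1:m]) <= k
    }, TRUE))
    p_exact <- min(1, 2 * cnt / 2^m)
    expect_equal(mcnemar(predA, predB, truth)$p, p_exact)
  }
})

test_that("logit truncation transforms p-values as stated", {
  expect_equal(logit_truncate(0.5), 0)
  expect_equal(logit_truncate(1), log(0.99 / 0.01))
  expect_equal(logit_truncate(1), 4.59512, tolerance = 1e-5)
  p <- c(0.001, 0.2, 0.5, 0.9, 0.98)
  expect_true(all(diff(logit_truncate(p)) > 0))
  expect_error(logit_truncate(0), "explicitly")
  expect_error(logit_truncate(1.2), "exceed")
})

test_that("the majority baseline predicts the modal class with marginal posteriors", {
  labels <- rep(0:5, times = table1_counts)
  bm <- baseline_majority(labels)
  expect_identical(bm$modal, 5L)       # the 40-count class
  pr <- predict(bm, NULL, n = 4)
  expect_true(all(pr$predicted == 5L))
  expect_equal(pr$posterior[1, ], table1_counts / 209,
               ignore_attr = TRUE)
  # uniform labels: tie broken by class order
  expect_identical(baseline_majority(c(2, 1, 2, 1))$modal, 1)
  expect_error(baseline_majority(integer(0)), "empty")
})

test_that("rank frequencies count rank occupancy across reshuffles", {
  rel <- list(c(a = 3, b = 2, c = 1), c(a = 3, b = 2, c = 1))
  rf <- rank_frequencies(rel, 3)
  expect_equal(unname(rf[1, ]), c(1, 0, 0))
  expect_true(all(abs(rowSums(rf) - 1) < 1e-12))
  # feature first in 7 of 10 reshuffles -> frequency 0.7 at rank 1
  rel10 <- c(rep(list(c(a = 9, b = 1)), 7), rep(list(c(a = 1, b = 9)), 3))
  rf10 <- rank_frequencies(rel10, 2)
  expect_equal(rf10["rank1", "a"], 0.7)
  expect_equal(rf10["rank2", "a"], 0.3)
  expect_error(rank_frequencies(list()), "empty")
  expect_error(rank_frequencies(list(1:2, 1:3)), "equal length")
})

test_that("weighted saliency pools maps by rank frequency", {
  m1 <- matrix(1, 4, 4); m2 <- matrix(3, 4, 4)
  rf <- rbind(rank1 = c(d1 = 1, d2 = 0), rank2 = c(d1 = 0, d2 = 1))
  # single dimension at frequency 1 on rank 1
  w1 <- weighted_saliency(list(d1 = m1, d2 = m2), rf, ranks = 1)
  expect_equal(w1$values, m1)
  # equal pooling over ranks 1 and 2 -> arithmetic mean
  w12 <- weighted_saliency(list(d1 = m1, d2 = m2), rf, ranks = 1:2)
  expect_equal(w12$values, matrix(2, 4, 4))
  expect_true(all(w12$values >= 0))
  expect_error(weighted_saliency(list(d1 = m1), rf, ranks = 1:2),
               "missing saliency map.*d2")
})

test_that("paired cross-testing aligns predictions across pipelines", {
  bf <- blob_fixture(n_per_class = 12, gap = 6, seed = 20)
  plan <- make_plan(bf$y, n_folds = 4, n_reshuffles = 2, seed = 3)
  ct <- cross_test(bf$X, bf$y, plan, "gpc", seed = 4)
  expect_identical(dim(ct$predicted), c(24L, 2L))
  expect_false(anyNA(ct$predicted))
  expect_identical(nrow(ct$metrics), 2L)
  expect_true(all(ct$metrics$acc >= 0 & ct$metrics$acc <= 100))
  expect_true(all(ct$metrics$mi >= 0 & ct$metrics$mi <= 1 + 1e-9))
  # separable blobs: far above the 50% majority rate, McNemar small
  expect_true(all(ct$metrics$acc > 90))
  expect_true(all(ct$metrics$mcnemar_p < 0.05))
  expect_length(ct$relevance, 2)
  expect_length(ct$relevance[[1]], 5)
})
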