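test_that("spec validation rejects bad configurations", {
  expect_error(synth_spec(n_per_class = c(0, 3)), "at least one")
  expect_error(synth_spec(image_side = 16), "image_side")
  expect_error(synth_spec(artifact_spec = list(
    artifact("pin-blob", prob = 1.5, intensity = 0.2))), "0, 1")
  expect_error(effect_region("dorsal", 0, NaN), "finite")
  expect_error(synth_spec(noise_sd = -1), "nonnegative")
})

test_that("regeneration with the same spec and seed is bit-identical", {
  sp <- tiny_spec(seed = 99)
  expect_identical(generate_dataset(sp), generate_dataset(sp))
})

test_that("per-class counts in the output match the generator settings exactly", {
  sp <- synth_spec(n_per_class = c(4L, 2L, 7L), seed = 3)
  ds <- generate_dataset(sp)
  expect_identical(as.vector(table(ds$labels)), c(4L, 2L, 7L))
  expect_true(all(ds$labels %in% 0:2))
})

test_that("with all variability off, every specimen is identical", {
  sp <- synth_spec(n_per_class = c(3L, 3L, 3L),
                   effect_regions = list(), artifact_spec = list(),
                   noise_sd = 0, jitter_sd = 0, seed = 5)
  ds <- generate_dataset(sp)
  for (n in 2:9) {
    expect_identical(ds$images[[n]], ds$images[[1]])
    expect_identical(ds$landmarks[[n]], ds$landmarks[[1]])
  }
})

test_that("images are valid grayscale and landmarks lie inside the image", {
  ds <- generate_dataset(tiny_spec(seed = 2))
  S <- ds$spec$image_side
  for (img in ds$images) {
    expect_true(all(img >= 0 & img <= 1))
    expect_identical(dim(img), c(S, S))
  }
  for (lm in ds$landmarks) {
    expect_identical(dim(lm), c(14L, 2L))
    expect_true(all(lm >= 0 & lm <= S - 1))
  }
})

test_that("a class effect changes images only inside the effect mask", {
  # dorsal amplitude for class 0 only, everything else switched off
  sp <- synth_spec(n_per_class = c(4L, 4L),
                   effect_regions = list(effect_region("dorsal", 0L, 5)),
                   artifact_spec = list(), noise_sd = 0, jitter_sd = 0,
                   seed = 7)
  ds <- generate_dataset(sp)
  m0 <- Reduce(`+`, ds$images[ds$labels == 0]) / 4
  m1 <- Reduce(`+`, ds$images[ds$labels == 1]) / 4
  dif <- abs(m0 - m1) > 1e-9
  expect_gt(sum(dif), 0)
  expect_true(all(dif[!ds$truth_effect_mask$dorsal] == FALSE))

  # landmark displacement confined to landmarks tied to the dorsal region
  l0 <- ds$landmarks[[1]]; l1 <- ds$landmarks[[5]]
  moved <- rowSums(abs(l0 - l1)) > 1e-9
  expect_true(all(names(which(moved)) %in% c("AOD", "POD")))
  expect_true(any(moved))
})

test_that("class-correlated artifacts land inside their truth masks", {
  sp <- synth_spec(n_per_class = c(3L, 3L),
                   effect_regions = list(),
                   artifact_spec = list(artifact("pin-blob",
                                                 prob = c(1, 0),
                                                 intensity = -0.4)),
                   noise_sd = 0, jitter_sd = 0, seed = 13)
  ds <- generate_dataset(sp)
  am <- ds$truth_artifact_mask[["pin-blob"]]
  d01 <- abs(ds$images[[1]] - ds$images[[4]]) > 1e-9
  expect_gt(sum(d01), 0)
  expect_true(all(d01[!am] == FALSE))
})

test_that("saliency fixtures have the stated structure", {
  m0a <- generate_saliency_fixture(32, "null", seed = 1)
  m0b <- generate_saliency_fixture(32, "null", seed = 2)
  # equal marginal mark distribution across seeds
  expect_gt(suppressWarnings(
    stats::ks.test(as.vector(m0a$values), as.vector(m0b$values))$p.value),
    0.01)
  # zero-amplitude cluster degenerates to the null map
  mc0 <- generate_saliency_fixture(32, "cluster", c(16, 16), 3,
                                   amplitude = 0, seed = 1)
  expect_identical(mc0$values, m0a$values)
  # a dominant bump puts the map maximum near the requested center
  mc <- generate_saliency_fixture(32, "cluster", c(10, 20), 3,
                                  amplitude = 50, seed = 1)
  ij <- which(mc$values == max(mc$values), arr.ind = TRUE)
  expect_lte(abs(ij[1, "col"] - 1 - 10), 3)  # x = col - 1
  expect_lte(abs(ij[1, "row"] - 1 - 20), 3)  # y = row - 1
  expect_error(generate_saliency_fixture(32, "cluster", c(40, 16), 3),
               "outside")
  expect_error(generate_saliency_fixture(8, "null"), "at least 16")
})

test_that("datasets round-trip through disk bit-exactly", {
  ds <- generate_dataset(tiny_spec(seed = 21, artifact_spec = list(
    artifact("dirt-specks", prob = 0.5, intensity = -0.3))))
  td <- withr::local_tempdir()
  write_dataset(ds, td)
  dr <- read_dataset(td)
  expect_identical(dr$images, ds$images)
  expect_identical(dr$labels, ds$labels)
  expect_equal(dr$landmarks, ds$landmarks, tolerance = 1e-12)
  expect_identical(dr$truth_artifact_mask, ds$truth_artifact_mask)
  expect_identical(dr$spec$n_per_class, ds$spec$n_per_class)
})

test_that("malformed dataset directories produce named I/O errors", {
  expect_error(read_dataset(withr::local_tempdir()), "no manifest")
  ds <- generate_dataset(tiny_spec(seed = 1))
  td <- withr::local_tempdir()
  write_dataset(ds, td)
  # truncate the landmark table to 13 pairs
  tab <- utils::read.csv(file.path(td, "landmarks.csv"))
  utils::write.csv(tab[, 1:28], file.path(td, "landmarks.csv"),
                   row.names = FALSE)
  expect_error(read_dataset(td), "spec0001")
})

test_that("the TPS dialect reader parses LM blocks", {
  td <- withr::local_tempdir()
  f <- file.path(td, "sample.tps")
  writeLines(c("LM=3", "1.0 2.0", "3.5 4.5", "5 6", "ID=fishA",
               "LM=3", "0 0", "1 1", "2 2"), f)
  tp <- read_tps(f)
  expect_identical(names(tp), c("fishA", "tps2"))
  expect_equal(tp$fishA[2, ], c(x = 3.5, y = 4.5))
  writeLines(c("3 landmarks follow", "1 2"), f)
  expect_error(read_tps(f), "expected LM=")
})
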