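# Pixel-wise permutation significance test for saliency maps.
#
# A saliency map is treated as a sample from a marked spatial point process:
# pixel coordinates carrying nonnegative importance marks.  Under the null
# hypothesis the locations form a homogeneous process, so reshuffling all
# pixel coordinates (equivalently, permuting the marks over the grid) yields
# null samples with the observed mark distribution but no spatial structure.
# Local mark mass is compared through a k x k Gaussian smoothing; the
# per-pixel p-value is the fraction of null samples whose smoothed value at
# that pixel reaches the observed smoothed value (ties count toward the
# null, making the test conservative).

gaussian_kernel_1d <- function(k) {
  h <- (k - 1) / 2
  sigma <- 0.3 * (h - 1) + 0.8   # default-bandwidth convention of common
  t <- -h:h                      # image-convolution routines
  w <- exp(-t^2 / (2 * sigma^2))
  list(w = w / sum(w), sigma = sigma)
}

# n x n band smoothing matrix with reflect-101 border handling
smoother_matrix <- function(n, k) {
  w <- gaussian_kernel_1d(k)$w
  h <- (k - 1) / 2
  Ks <- matrix(0, n, n)
  for (i in 0:(n - 1)) {
    for (t in -h:h) {
      j <- i + t
      if (j < 0) j <- -j
      if (j > n - 1) j <- 2 * (n - 1) - j
      Ks[i + 1, j + 1] <- Ks[i + 1, j + 1] + w[t + h + 1]
    }
  }
  Ks
}

#' Smooth a saliency map with a Gaussian kernel
#'
#' Separable k x k Gaussian convolution with bandwidth
#' `sigma = 0.3 * ((k - 1) / 2 - 1) + 0.8` and reflect border padding.
#' Mass-preserving on constant inputs; `k = 1` is the identity.
#'
#' @param map A [saliency_map()] or plain matrix.
#' @param k Odd kernel side, `1 <= k <= min(dim)`.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_map <- function(map, k = 5L) {
  v <- sal_values(map)
  if (k %% 2 == 0) ms_stop("kernel size k must be odd", "morphsal_input_error")
  if (k < 1 || k > min(dim(v)))
    ms_stop("kernel size k out of range", "morphsal_input_error")
  if (k == 1) return(v)
  Ky <- smoother_matrix(nrow(v), k)
  Kx <- smoother_matrix(ncol(v), k)
  Ky %*% v %*% t(Kx)
}

#' Draw one null sample of a saliency map
#'
#' Uniformly permutes the importance marks over the pixel grid (coordinate
#' reshuffling), preserving the mark multiset exactly.
#'
#' @param map A [saliency_map()] or matrix.
#' @return Matrix of the same shape.
#' @export
null_sample <- function(map) {
  v <- sal_values(map)
  matrix(v[sample.int(length(v))], nrow = nrow(v))
}

#' Permutation p-value map for a saliency map
#'
#' Compares the Gaussian-smoothed observed map against `n_resamples`
#' smoothed coordinate-reshuffled null maps; the p-value at each pixel is
#' the fraction of null samples at least as large there (one-sided, ties
#' toward the null).  Pixels with `p < threshold` form the significance
#' mask.
#'
#' @param map A [saliency_map()] or matrix of finite nonnegative marks.
#' @param k Odd Gaussian kernel side (default 5).
#' @param n_resamples Number of null permutations N (default 1e4).
#' @param threshold Masking threshold on the raw per-pixel p-value
#'   (default 0.001).
#' @param seed Integer seed for the permutations.
#' @param adjust `"none"` (raw per-pixel p-values, the default) or `"BH"`
#'   (Benjamini-Hochberg adjustment before masking).
#' @return Object of class `pvalue_map`: `pvals` (values in 0, 1/N, ..., 1),
#'   `mask`, `n_resamples`, `kernel_size`, `sigma`, `threshold`, `seed`.
#' @export
pvalue_map <- function(map, k = 5L, n_resamples = 10000L, threshold = 0.001,
                       seed = 1L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  v <- sal_values(map)
  if (!all(is.finite(v)))
    ms_stop("saliency marks must be finite", "morphsal_input_error")
  if (n_resamples < 1 || threshold <= 0 || threshold >= 1)
    ms_stop("need n_resamples >= 1 and threshold in (0, 1)",
            "morphsal_input_error")
  set.seed(seed)
  H <- nrow(v); W <- ncol(v)
  Ky <- if (k > 1) smoother_matrix(H, k) else diag(H)
  Kxt <- if (k > 1) t(smoother_matrix(W, k)) else diag(W)
  g1 <- Ky %*% v %*% Kxt
  cnt <- matrix(0L, H, W)
  vv <- as.vector(v)
  n <- length(vv)
  for (b in seq_len(n_resamples)) {
    g0 <- Ky %*% matrix(vv[sample.int(n)], H, W) %*% Kxt
    cnt <- cnt + (g0 >= g1)
  }
  pv <- cnt / n_resamples
  pmask <- if (adjust == "BH") {
    matrix(stats::p.adjust(pv, method = "BH"), H, W) < threshold
  } else pv < threshold
  structure(list(pvals = pv, mask = pmask, n_resamples = n_resamples,
                 kernel_size = as.integer(k),
                 sigma = if (k > 1) gaussian_kernel_1d(k)$sigma else 0,
                 threshold = threshold, seed = as.integer(seed),
                 adjust = adjust),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat(sprintf(
    "pvalue_map: %dx%d, k=%d (sigma=%.2f), N=%d, threshold=%g, %d significant px\n",
    nrow(x$pvals), ncol(x$pvals), x$kernel_size, x$sigma, x$n_resamples,
    x$threshold, sum(x$mask)))
  invisible(x)
}

#' Apply a significance mask to a saliency map
#'
#' @param map A [saliency_map()] or matrix.
#' @param pmap A `pvalue_map` of the same shape.
#' @param mode `"zero-out"` sets non-significant saliency values to zero
#'   (the data-set-level convention); `"overlay"` returns the binary mask
#'   for compositing on a specimen image (the per-sample convention).
#' @return Matrix (zero-out) or logical matrix (overlay).
#' @export
apply_mask <- function(map, pmap, mode = c("zero-out", "overlay")) {
  mode <- match.arg(mode)
  v <- sal_values(map)
  if (!all(dim(v) == dim(pmap$pvals)))
    ms_stop("map and p-value map shapes differ", "morphsal_input_error")
  if (mode == "overlay") pmap$mask else v * pmap$mask
}

#' Read / write saliency matrices as plain text
#'
#' Plain CSV matrix files (no header) interoperable with externally produced
#' saliency maps, e.g. CNN relevance or gradient-based maps.
#'
#' @param path File path.
#' @param source_tag Tag recorded on the map read.
#' @return `read_saliency` returns a [saliency_map()].
#' @export
read_saliency <- function(path, source_tag = basename(path)) {
  if (!file.exists(path))
    ms_stop(sprintf("saliency file '%s' not found", path), "morphsal_io_error")
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  saliency_map(m, source_tag)
}

#' @rdname read_saliency
#' @param map A [saliency_map()] or matrix to write.
#' @export
write_saliency <- function(map, path) {
  utils::write.table(sal_values(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a p-value map with its metadata sidecar
#'
#' Writes the p-value matrix and binary mask as CSV plus a `*.meta.txt`
#' sidecar recording kernel size, bandwidth, resample count, seed and
#' threshold.
#'
#' @param pmap A `pvalue_map`.
#' @param prefix Output path prefix.
#' @export
write_pvalue_map <- function(pmap, prefix) {
  utils::write.table(pmap$pvals, paste0(prefix, "_pvals.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(pmap$mask * 1L, paste0(prefix, "_mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(paste0("k=", pmap$kernel_size),
               paste0("sigma=", pmap$sigma),
               paste0("n_resamples=", pmap$n_resamples),
               paste0("threshold=", pmap$threshold),
               paste0("seed=", pmap$seed),
               paste0("adjust=", pmap$adjust)),
             paste0(prefix, ".meta.txt"))
  invisible(prefix)
}
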