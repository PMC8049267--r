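# Generalized Procrustes analysis: converts raw 2-D landmark configurations
# to shapes that are invariant to location, scale and rotation, and flattens
# the aligned shapes into the classifier feature matrix.
#
# A configuration is a 2 x M matrix whose columns are landmarks (x over y).
# The three-step alignment: (1) translate each centroid to the origin,
# (2) rescale to unit centroid size, (3) rotate each shape into agreement
# with the current mean shape (SVD orthogonal-Procrustes solution restricted
# to proper rotations), iterating rotation against the re-estimated mean
# until the mean stabilizes.  The mean is not re-normalized between
# iterations: scale is fixed in step (2) only.

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid, i.e. `sqrt(trace(Y' C' C Y))` with `C` the centering
#' matrix; the size measure that GPA normalizes to 1.
#'
#' @param config A 2 x M matrix of landmark columns, or an M x 2 matrix of
#'   landmark rows (auto-detected; M >= 3 assumed in the ambiguous 2 x 2
#'   case to be column-landmarks).
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  Y <- as_config(config)
  if (!all(is.finite(Y)))
    ms_stop("landmark coordinates must be finite", "morphsal_input_error")
  Yc <- Y - rowMeans(Y)
  s <- sqrt(sum(Yc^2))
  if (s <= .Machine$double.eps * 100)
    ms_stop("degenerate configuration: all landmarks coincide",
            "morphsal_input_error")
  s
}

# normalize input to a 2 x M matrix of landmark columns
as_config <- function(config) {
  Y <- as.matrix(config)
  if (nrow(Y) != 2 && ncol(Y) == 2) Y <- t(Y)
  if (nrow(Y) != 2 || ncol(Y) < 3)
    ms_stop("a configuration needs 2 rows (x, y) and at least 3 landmarks",
            "morphsal_input_error")
  Y
}

# proper rotation G (2 x 2, det +1) maximizing agreement between G Z and mu
procrustes_rotation <- function(Z, mu) {
  A <- Z %*% t(mu)                      # maximize tr(G A)
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, d)) %*% t(sv$u)
}

#' Generalized Procrustes analysis
#'
#' Aligns a set of landmark configurations by translation, scaling and
#' rotation (classic iterative alignment to the evolving mean shape) and
#' builds the flattened N x 2M feature matrix with landmark m stored as the
#' column pair `x_m, y_m`.
#'
#' @param configs List of landmark configurations (each 2 x M or M x 2).
#' @param tol Convergence tolerance on the Frobenius change of the mean
#'   shape between iterations.
#' @param max_iter Maximum number of alignment iterations.
#' @return An object of class `shape_set`: `shapes` (list of 2 x M aligned
#'   shapes, centroid at the origin, unit centroid size), `mean_shape`,
#'   `rotations` (per-specimen proper 2 x 2 rotations, accumulated),
#'   `feature_matrix` (N x 2M), `n_iter`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 1)
    ms_stop("need at least one configuration", "morphsal_input_error")
  Ys <- lapply(configs, as_config)
  M <- ncol(Ys[[1]])
  if (!all(vapply(Ys, ncol, 0L) == M))
    ms_stop("all configurations must have the same number of landmarks",
            "morphsal_input_error")
  N <- length(Ys)
  # steps 1 + 2: center and scale once
  Zs <- lapply(Ys, function(Y) {
    Yc <- Y - rowMeans(Y)
    Yc / centroid_size(Y)
  })
  rots <- rep(list(diag(2)), N)
  mu <- Reduce(`+`, Zs) / N
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (n in seq_len(N)) {
      G <- procrustes_rotation(Zs[[n]], mu)
      Zs[[n]] <- G %*% Zs[[n]]
      rots[[n]] <- G %*% rots[[n]]
    }
    mu_new <- Reduce(`+`, Zs) / N
    if (sqrt(sum((mu_new - mu)^2)) < tol) {
      mu <- mu_new
      converged <- TRUE
      break
    }
    mu <- mu_new
  }
  if (!converged)
    warning("GPA did not converge within max_iter; returning best iterate")
  X <- t(vapply(Zs, function(Z) as.vector(Z), numeric(2 * M)))
  acr <- if (M == 14) landmark_acronyms() else paste0("L", seq_len(M))
  colnames(X) <- as.vector(rbind(paste0(acr, "_x"), paste0(acr, "_y")))
  nm <- names(configs)
  if (!is.null(nm)) rownames(X) <- nm
  structure(list(shapes = Zs, mean_shape = mu, rotations = rots,
                 feature_matrix = X, n_iter = it, converged = converged),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("shape_set: %d shapes, %d landmarks, %d GPA iterations%s\n",
              length(x$shapes), ncol(x$mean_shape), x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Write a GPA feature matrix as CSV
#'
#' @param shapes A `shape_set` from [gpa()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(shapes, path) {
  utils::write.csv(as.data.frame(shapes$feature_matrix), path,
                   row.names = FALSE)
  invisible(path)
}
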