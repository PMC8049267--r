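# Aggregation of automatic-relevance-determination metrics.
#
# MLP prior scales combine across weight groups by summing squares.  GPC
# inverse squared length scales act nonlinearly inside the covariance, so a
# group of inputs is summarized by the single inverse length scale whose
# isotropic covariance best matches the anisotropic one over the observed
# group samples; the least-squares optimum has the closed form implemented
# in combine_gpc_lengthscales().

#' Combine MLP relevance scales by summed squares
#'
#' @param sigma1 Nonnegative vector of input-to-hidden prior scales.
#' @param sigma2 Nonnegative vector of input-to-output prior scales (same
#'   length).
#' @return Element-wise `sqrt(sigma1^2 + sigma2^2)`.
#' @export
combine_mlp_relevance <- function(sigma1, sigma2) {
  if (length(sigma1) != length(sigma2))
    ms_stop("relevance vectors must have equal length", "morphsal_input_error")
  if (any(sigma1 < 0) || any(sigma2 < 0))
    ms_stop("relevance scales must be nonnegative", "morphsal_input_error")
  sqrt(sigma1^2 + sigma2^2)
}

#' Combine GPC inverse length scales over an input group
#'
#' For inverse squared length scales `alphas` of a group of inputs and the
#' observed sample vectors `eta_n` restricted to that group, returns the
#' scalar
#' \deqn{\hat\alpha = \frac{\sum_n \eta_n' L \eta_n \cdot \eta_n'\eta_n}
#'                         {\sum_n (\eta_n'\eta_n)^2}, \quad
#'        L = \mathrm{diag}(\alpha)}
#' which is the least-squares minimizer of
#' \eqn{\sum_n (\eta_n' L \eta_n - \alpha\,\eta_n'\eta_n)^2}.
#'
#' @param alphas Nonnegative vector of length j + 1.
#' @param group_samples Matrix with one sample vector per row (N x (j + 1)),
#'   or a list of such vectors; at least one must be nonzero.
#' @return Scalar combined inverse length scale.
#' @export
combine_gpc_lengthscales <- function(alphas, group_samples) {
  if (is.list(group_samples))
    group_samples <- do.call(rbind, group_samples)
  eta <- as.matrix(group_samples)
  if (ncol(eta) != length(alphas))
    ms_stop("sample vectors must match the group size", "morphsal_input_error")
  if (any(alphas < 0))
    ms_stop("inverse length scales must be nonnegative", "morphsal_input_error")
  qn <- rowSums(eta^2)                        # eta' eta
  if (all(qn == 0))
    ms_stop("all group samples are zero; combined scale undefined",
            "morphsal_input_error")
  wn <- as.vector(eta^2 %*% alphas)           # eta' L eta
  sum(wn * qn) / sum(qn^2)
}

#' Per-landmark relevance from an ARD profile
#'
#' Aggregates the x/y coordinate-pair relevances of each landmark: summed
#' squares of the four prior scales for the MLP; the combined inverse
#' length scale (see [combine_gpc_lengthscales()]) for the GPC, which needs
#' the observed feature samples.
#'
#' @param profile For `mode = "gpc"`: a `gpc_fit` or a numeric alpha vector
#'   of length 2M (feature-matrix column order `x1,y1,...,xM,yM`).  For
#'   `mode = "mlp"`: an `hmc_mlp_fit` or a list with elements `sigma1`,
#'   `sigma2` of length 2M.
#' @param mode `"gpc"` or `"mlp"`.
#' @param samples N x 2M feature matrix (required for `mode = "gpc"`).
#' @param acronyms Landmark names attached to the result (default the
#'   standard 14 when M = 14).
#' @return Named numeric vector of M landmark relevances.
#' @export
landmark_relevance <- function(profile, mode = c("gpc", "mlp"),
                               samples = NULL, acronyms = NULL) {
  mode <- match.arg(mode)
  if (mode == "gpc") {
    alpha <- if (inherits(profile, "gpc_fit")) profile$ard_profile$alpha
             else as.numeric(profile)
    if (length(alpha) %% 2 != 0)
      ms_stop("feature count must be even (x/y pairs per landmark)",
              "morphsal_input_error")
    M <- length(alpha) / 2
    if (is.null(samples))
      ms_stop("GPC landmark aggregation needs the feature samples",
              "morphsal_input_error")
    samples <- as.matrix(samples)
    rel <- vapply(seq_len(M), function(m) {
      idx <- c(2 * m - 1, 2 * m)
      combine_gpc_lengthscales(alpha[idx], samples[, idx, drop = FALSE])
    }, 0)
  } else {
    if (inherits(profile, "hmc_mlp_fit")) profile <- profile$ard_profile
    s1 <- profile$sigma1; s2 <- profile$sigma2
    if (length(s1) %% 2 != 0)
      ms_stop("feature count must be even (x/y pairs per landmark)",
              "morphsal_input_error")
    M <- length(s1) / 2
    rel <- vapply(seq_len(M), function(m) {
      idx <- c(2 * m - 1, 2 * m)
      sqrt(sum(s1[idx]^2 + s2[idx]^2))
    }, 0)
  }
  names(rel) <- acronyms %||%
    (if (M == 14) landmark_acronyms() else paste0("L", seq_len(M)))
  rel
}
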