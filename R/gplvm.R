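# Sparse variational Gaussian process latent variable model (Bayesian GP-LVM)
# for image feature extraction, with ARD ranking of latent dimensions,
# projection of latent variability to image-space saliency maps, and
# screening of artifact-driven dimensions.
#
# Model: each column y_d of the N x D data matrix is a zero-mean GP over the
# latent inputs X with squared-exponential ARD covariance
#   k(x, x') = sf2 * exp(-0.5 * sum_l alpha_l (x_l - x'_l)^2)
# plus Gaussian noise of precision beta.  X carries a standard-normal prior;
# the posterior is approximated by a factorized Gaussian Q(X) with means mu_n
# and diagonal covariances s_n.  Sparsity comes from M inducing inputs Z; the
# collapsed variational lower bound on log p(Y) (the classic inducing-point
# bound with kernel expectation "psi statistics") is maximized jointly over
# {mu, s, Z, alpha, sf2, beta} by L-BFGS-B with analytic gradients.
#
# The D-dimensional data enters the bound only through Y Y' (N x N) and
# tr(Y Y'), so evaluations cost O(N M^2 L + M^3) regardless of D.

JITTER <- 1e-6

# Pack/unpack the optimization vector:
# c(mu [N*L], log s [N*L], Z [M*L], log alpha [L], log sf2, log beta)
gplvm_unpack <- function(par, N, L, M) {
  i <- 0
  mu <- matrix(par[i + seq_len(N * L)], N, L); i <- i + N * L
  s <- matrix(exp(par[i + seq_len(N * L)]), N, L); i <- i + N * L
  Z <- matrix(par[i + seq_len(M * L)], M, L); i <- i + M * L
  alpha <- exp(par[i + seq_len(L)]); i <- i + L
  sf2 <- exp(par[i + 1]); beta <- exp(par[i + 2])
  list(mu = mu, s = s, Z = Z, alpha = alpha, sf2 = sf2, beta = beta)
}

chol_safe <- function(A) {
  for (j in c(0, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(A + diag(j, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

# Evaluate the negative bound and its gradient.
# YYt: N x N data Gram matrix; trYY = tr(Y Y'); D: data dimension.
gplvm_obj <- function(par, N, L, M, D, YYt, trYY) {
  p <- gplvm_unpack(par, N, L, M)
  mu <- p$mu; s <- p$s; Z <- p$Z; alpha <- p$alpha
  sf2 <- p$sf2; beta <- p$beta
  M2 <- M * M

  # --- psi statistics ---
  logPsi1 <- matrix(log(sf2), N, M)
  logW <- matrix(0, N, M2)
  for (l in seq_len(L)) {
    al <- alpha[l]; mul <- mu[, l]; sl <- s[, l]; Zl <- Z[, l]
    cl <- 1 + al * sl
    Dml <- outer(mul, Zl, "-")
    logPsi1 <- logPsi1 - 0.5 * log(cl) - 0.5 * al * Dml^2 / cl
    dn <- 1 + 2 * al * sl
    zbar <- as.vector(outer(Zl, Zl, "+")) / 2
    dist2 <- as.vector(outer(Zl, Zl, "-"))^2
    Q <- outer(mul, zbar, "-")
    logW <- logW - 0.5 * log(dn) - al * rep(dist2, each = N) / 4 -
      al * Q^2 / dn
  }
  Psi1 <- exp(logPsi1)
  W <- exp(logW)
  Psi2 <- sf2^2 * matrix(colSums(W), M, M)
  Psi2 <- (Psi2 + t(Psi2)) / 2
  psi0 <- N * sf2

  distK <- matrix(0, M, M)
  for (l in seq_len(L)) distK <- distK + alpha[l] * outer(Z[, l], Z[, l], "-")^2
  Kc <- sf2 * exp(-0.5 * distK)
  Kmm <- Kc + diag(JITTER * sf2 + JITTER, M)

  Lm <- chol_safe(Kmm)
  B <- Kmm + beta * Psi2
  Lb <- chol_safe(B)
  if (is.null(Lm) || is.null(Lb)) return(list(value = NA_real_))

  Kinv <- chol2inv(Lm)
  Binv <- chol2inv(Lb)
  P <- YYt %*% Psi1                      # N x M
  Tm <- crossprod(Psi1, P)               # M x M
  trBinvT <- sum(Binv * Tm)
  trKinvPsi2 <- sum(Kinv * Psi2)
  trBinvPsi2 <- sum(Binv * Psi2)

  F1 <- D * (N / 2 * log(beta) - N / 2 * log(2 * pi) +
               sum(log(diag(Lm))) - sum(log(diag(Lb)))) -
    beta / 2 * trYY + beta^2 / 2 * trBinvT -
    D * beta / 2 * psi0 + D * beta / 2 * trKinvPsi2
  KL <- 0.5 * sum(mu^2 + s - log(s) - 1)
  Fv <- F1 - KL
  if (!is.finite(Fv)) return(list(value = NA_real_))

  # --- gradients ---
  E <- Binv %*% Tm %*% Binv
  G1 <- beta^2 * (P %*% Binv)                                   # dF/dPsi1
  G2 <- -(D * beta / 2) * Binv + (D * beta / 2) * Kinv -
    (beta^3 / 2) * E                                            # dF/dPsi2
  Gk <- (D / 2) * Kinv - (D / 2) * Binv - (beta^2 / 2) * E -
    (D * beta / 2) * (Kinv %*% Psi2 %*% Kinv)                   # dF/dKmm

  dbeta <- D * N / (2 * beta) - (D / 2) * trBinvPsi2 - D * psi0 / 2 +
    (D / 2) * trKinvPsi2 + beta * trBinvT -
    (beta^2 / 2) * sum(E * Psi2) - trYY / 2

  H1 <- G1 * Psi1
  g2v <- sf2^2 * as.vector((G2 + t(G2)) / 2)
  Wg <- W * rep(g2v, each = N)
  GkK <- Gk * Kc

  gmu <- matrix(0, N, L); gs <- matrix(0, N, L); gz <- matrix(0, M, L)
  galpha <- numeric(L)
  rsH1 <- rowSums(H1)
  rsWg <- rowSums(Wg)
  csWg <- colSums(Wg)
  for (l in seq_len(L)) {
    al <- alpha[l]; mul <- mu[, l]; sl <- s[, l]; Zl <- Z[, l]
    cl <- 1 + al * sl
    Dml <- outer(mul, Zl, "-")
    H1D <- H1 * Dml
    rsH1D <- rowSums(H1D)
    rsH1D2 <- rowSums(H1D * Dml)
    gmu1 <- -al * rsH1D / cl
    gs1 <- -0.5 * al * rsH1 / cl + 0.5 * al^2 * rsH1D2 / cl^2
    gz1 <- al * colSums(H1D / cl)
    ga1 <- sum(-0.5 * sl * rsH1 / cl - 0.5 * rsH1D2 / cl^2)

    dn <- 1 + 2 * al * sl
    zbar <- as.vector(outer(Zl, Zl, "+")) / 2
    dist2 <- as.vector(outer(Zl, Zl, "-"))^2
    Q <- outer(mul, zbar, "-")
    WgQ <- Wg * Q
    rsWgQ <- rowSums(WgQ)
    rsWgQ2 <- rowSums(WgQ * Q)
    gmu2 <- -2 * al * rsWgQ / dn
    gs2 <- -al * rsWg / dn + 2 * al^2 * rsWgQ2 / dn^2
    ga2 <- -sum(sl * rsWg / dn) - sum(csWg * dist2) / 4 -
      sum(rsWgQ2 / dn^2)
    Smat <- matrix(csWg, M, M)
    A1 <- matrix(colSums(Wg * (mul / dn)), M, M)
    A0 <- matrix(colSums(Wg / dn), M, M)
    Zbar <- matrix(zbar, M, M)
    term1 <- -al / 2 * (Zl * rowSums(Smat) - as.vector(Smat %*% Zl))
    term2 <- al * (rowSums(A1) - rowSums(A0 * Zbar))
    gz2 <- 2 * (term1 + term2)

    gzK <- -2 * al * (Zl * rowSums(GkK) - as.vector(GkK %*% Zl))
    gaK <- -0.5 * sum(GkK * outer(Zl, Zl, "-")^2)

    gmu[, l] <- gmu1 + gmu2 - mul
    gs[, l] <- gs1 + gs2 - 0.5 * (1 - 1 / sl)
    gz[, l] <- gz1 + gz2 + gzK
    galpha[l] <- ga1 + ga2 + gaK
  }
  dsf2 <- sum(H1) / sf2 + 2 * sum(G2 * Psi2) / sf2 - D * beta / 2 * N +
    sum(Gk * Kc) / sf2

  grad <- c(gmu, gs * s, gz, galpha * alpha, dsf2 * sf2, dbeta * beta)
  list(value = Fv, grad = grad)
}

#' Fit a sparse variational GP-LVM
#'
#' Learns a low-dimensional latent representation of a data matrix
#' (typically flattened grayscale images) by maximizing the collapsed
#' variational lower bound of a sparse Gaussian process latent variable
#' model with squared-exponential ARD covariance.  Latent means are
#' initialized from the leading principal components; all variational
#' parameters and kernel hyperparameters are then optimized jointly with
#' L-BFGS-B.
#'
#' @param images N x D numeric matrix (rows = specimens, columns = pixels),
#'   e.g. from [flatten_images()].  An `img_dim` attribute (rows, cols), if
#'   present, is carried into the fit for image-space projections.
#' @param latent_dim Number of latent dimensions L.
#' @param n_inducing Number of inducing inputs M (2 <= M <= N).
#' @param iterations Maximum L-BFGS-B iterations.
#' @param seed Integer seed (initialization of inducing inputs).
#' @return An object of class `gplvm_fit`: `means` (N x L posterior means),
#'   `covariances` (N x L posterior variances, diagonal), `inv_length_scales`
#'   (ARD weights alpha), `signal_variance`, `noise_precision`,
#'   `inducing_inputs`, `bound`, `bound_init`, `latent_dim`, `n_inducing`,
#'   `data_dim`, plus the fitted projection operator used by
#'   [project_dimension()].
#' @export
fit_gplvm <- function(images, latent_dim = 12L, n_inducing = 40L,
                      iterations = 500L, seed = 1L) {
  Y <- as.matrix(images)
  img_dim <- attr(images, "img_dim")
  N <- nrow(Y); D <- ncol(Y); L <- as.integer(latent_dim)
  M <- as.integer(n_inducing)
  if (M > N) ms_stop("n_inducing must not exceed the number of samples",
                     "morphsal_input_error")
  if (M < 2 || D < 1 || L < 1)
    ms_stop("need n_inducing >= 2, latent_dim >= 1 and D >= 1",
            "morphsal_input_error")
  if (!all(is.finite(Y)))
    ms_stop("pixel values must be finite", "morphsal_input_error")
  set.seed(seed)
  col_means <- colMeans(Y)
  Yc <- sweep(Y, 2, col_means)
  YYt <- tcrossprod(Yc)
  trYY <- sum(diag(YYt))

  # PCA init through the N x N Gram matrix (D never materialized)
  eg <- eigen(YYt, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(L), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(L)]), L)
  sds <- apply(scores, 2, stats::sd)
  sds[sds < 1e-8] <- 1
  mu0 <- sweep(scores, 2, sds, "/")
  mu0 <- mu0 + matrix(stats::rnorm(N * L, 0, 1e-3), N, L)
  s0 <- matrix(0.5, N, L)
  Z0 <- mu0[sample.int(N, M), , drop = FALSE] +
    matrix(stats::rnorm(M * L, 0, 1e-3), M, L)
  # unit-scale initialization (latent means standardized to unit variance,
  # kernel variance and noise precision 1): robust for data whose values are
  # O(1), e.g. grayscale images and aligned shape coordinates
  par0 <- c(mu0, log(s0), Z0, rep(log(1), L), log(1), log(1))

  # box bounds on the log-parameters keep the line search out of overflow
  # regions; a transiently infeasible evaluation gets a finite penalty, and
  # only a persistent failure aborts the fit
  np <- length(par0)
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  idx_logs <- N * L + seq_len(N * L)
  idx_hyp <- 2 * N * L + M * L + seq_len(L + 2)
  lower[idx_logs] <- -15; upper[idx_logs] <- 5
  lower[idx_hyp] <- -15; upper[idx_hyp] <- 15

  n_eval <- 0L; n_bad <- 0L
  cache <- new.env(parent = emptyenv())
  evalf <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    n_eval <<- n_eval + 1L
    res <- gplvm_obj(par, N, L, M, D, YYt, trYY)
    if (!is.finite(res$value)) {
      n_bad <<- n_bad + 1L
      if (n_bad > 50L)
        ms_stop(sprintf("non-finite bound at evaluation %d", n_eval),
                "morphsal_numeric_error")
      res <- list(value = -1e12, grad = rep(0, length(par)))
    } else n_bad <<- 0L
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) -evalf(par)$value
  gr <- function(par) -evalf(par)$grad
  bound_init <- -fn(par0)
  if (!is.finite(bound_init) || bound_init <= -1e12)
    ms_stop("non-finite bound at initialization", "morphsal_numeric_error")
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = as.integer(iterations)))
  p <- gplvm_unpack(opt$par, N, L, M)
  bound <- -opt$value

  # projection operator for the posterior predictive mean:
  # f(x*) = k(x*, Z) %*% Aproj + col_means
  logPsi1 <- matrix(log(p$sf2), N, M)
  for (l in seq_len(L)) {
    cl <- 1 + p$alpha[l] * p$s[, l]
    Dml <- outer(p$mu[, l], p$Z[, l], "-")
    logPsi1 <- logPsi1 - 0.5 * log(cl) - 0.5 * p$alpha[l] * Dml^2 / cl
  }
  Psi1 <- exp(logPsi1)
  logW <- matrix(0, N, M * M)
  for (l in seq_len(L)) {
    al <- p$alpha[l]; dn <- 1 + 2 * al * p$s[, l]
    zbar <- as.vector(outer(p$Z[, l], p$Z[, l], "+")) / 2
    dist2 <- as.vector(outer(p$Z[, l], p$Z[, l], "-"))^2
    Q <- outer(p$mu[, l], zbar, "-")
    logW <- logW - 0.5 * log(dn) - al * rep(dist2, each = N) / 4 -
      al * Q^2 / dn
  }
  Psi2 <- p$sf2^2 * matrix(colSums(exp(logW)), M, M)
  distK <- matrix(0, M, M)
  for (l in seq_len(L))
    distK <- distK + p$alpha[l] * outer(p$Z[, l], p$Z[, l], "-")^2
  Kmm <- p$sf2 * exp(-0.5 * distK) + diag(JITTER * p$sf2 + JITTER, M)
  B <- Kmm + p$beta * Psi2
  Lb <- chol_safe(B)
  Aproj <- p$beta * backsolve(Lb, forwardsolve(t(Lb), crossprod(Psi1, Yc)))

  structure(list(means = p$mu, covariances = p$s,
                 inv_length_scales = p$alpha,
                 signal_variance = p$sf2, noise_precision = p$beta,
                 inducing_inputs = p$Z, bound = bound,
                 bound_init = bound_init,
                 latent_dim = L, n_inducing = M, data_dim = D,
                 col_means = col_means, Aproj = Aproj,
                 img_dim = img_dim, convergence = opt$convergence,
                 n_eval = n_eval),
            class = "gplvm_fit")
}

#' @export
print.gplvm_fit <- function(x, ...) {
  cat(sprintf("gplvm_fit: L=%d latent dims, M=%d inducing, D=%d, bound=%.2f\n",
              x$latent_dim, x$n_inducing, x$data_dim, x$bound))
  cat("  ARD weights (alpha):",
      paste(sprintf("%.3g", x$inv_length_scales), collapse = " "), "\n")
  invisible(x)
}

#' Flatten an image stack to an N x D matrix
#'
#' @param images List of equally sized image matrices, or a `synth_dataset`.
#' @return N x D matrix with an `img_dim` attribute (rows, cols).  Pixels are
#'   stored column-major, matching `as.vector()` of the image matrix.
#' @export
flatten_images <- function(images) {
  if (inherits(images, "synth_dataset")) images <- images$images
  dm <- dim(images[[1]])
  Y <- t(vapply(images, as.vector, numeric(prod(dm))))
  attr(Y, "img_dim") <- dm
  Y
}

#' Select latent dimension and inducing-point count
#'
#' Sweeps the inducing-point count at a fixed latent dimension until the
#' optimized bound plateaus (relative improvement to the next candidate
#' below `plateau_tol`), then selects the latent dimension maximizing the
#' bound at that inducing count.
#'
#' @param images N x D data matrix.
#' @param latent_dims Ascending candidate latent dimensions.
#' @param inducing_counts Ascending candidate inducing-point counts.
#' @param sweep_latent_dim Latent dimension used during the inducing sweep
#'   (default: largest candidate).
#' @param plateau_tol Relative-improvement threshold defining the plateau.
#' @param iterations,seed Passed to [fit_gplvm()].
#' @return List with `latent_dim`, `n_inducing`, and the audit traces
#'   `bound_by_inducing`, `bound_by_latent`.
#' @export
select_model <- function(images, latent_dims, inducing_counts,
                         sweep_latent_dim = max(latent_dims),
                         plateau_tol = 0.01, iterations = 200L, seed = 1L) {
  latent_dims <- sort(unique(as.integer(latent_dims)))
  inducing_counts <- sort(unique(as.integer(inducing_counts)))
  if (length(latent_dims) == 1 && length(inducing_counts) == 1)
    warning("single candidate; returned as-is")
  bM <- vapply(inducing_counts, function(m)
    fit_gplvm(images, sweep_latent_dim, m, iterations, seed)$bound, 0)
  Mhat <- inducing_counts[length(inducing_counts)]
  if (length(inducing_counts) > 1) {
    for (i in seq_len(length(inducing_counts) - 1)) {
      if ((bM[i + 1] - bM[i]) / abs(bM[i]) < plateau_tol) {
        Mhat <- inducing_counts[i]
        break
      }
    }
  } else Mhat <- inducing_counts[1]
  bL <- vapply(latent_dims, function(l)
    fit_gplvm(images, l, Mhat, iterations, seed)$bound, 0)
  Lhat <- latent_dims[which.max(bL)]
  list(latent_dim = Lhat, n_inducing = Mhat,
       bound_by_inducing = stats::setNames(bM, inducing_counts),
       bound_by_latent = stats::setNames(bL, latent_dims))
}

#' Rank latent dimensions by ARD relevance
#'
#' @param rep A `gplvm_fit`.
#' @return Integer vector: dimension indices ordered by decreasing ARD
#'   weight alpha, ties broken by ascending index.
#' @export
rank_dimensions <- function(rep) {
  a <- rep$inv_length_scales
  order(-a, seq_along(a))
}

# predictive mean of the decoder at new latent points (rows of Xstar)
gplvm_predict_mean <- function(fit, Xstar) {
  L <- fit$latent_dim
  dist <- matrix(0, nrow(Xstar), fit$n_inducing)
  for (l in seq_len(L))
    dist <- dist + fit$inv_length_scales[l] *
      outer(Xstar[, l], fit$inducing_inputs[, l], "-")^2
  Kxm <- fit$signal_variance * exp(-0.5 * dist)
  sweep(Kxm %*% fit$Aproj, 2, fit$col_means, "+")
}

#' Project a latent dimension into image space
#'
#' Fixes all latent coordinates at the sample mean except dimension `dim`,
#' which sweeps an equally spaced grid spanning mean +/- 2 sd of that
#' dimension's posterior means; each grid point is decoded through the
#' posterior predictive mean, and the per-pixel standard deviation across
#' the sweep becomes the saliency value.
#'
#' @param rep A `gplvm_fit` (with a stored image geometry).
#' @param dim Latent dimension index (1-based).
#' @param n_grid Number of sweep points.
#' @param img_dim Image (rows, cols); defaults to the geometry stored at
#'   fit time.
#' @return A [saliency_map()].
#' @export
project_dimension <- function(rep, dim, n_grid = 11L, img_dim = rep$img_dim) {
  if (dim < 1 || dim > rep$latent_dim)
    ms_stop("latent dimension out of range", "morphsal_input_error")
  if (is.null(img_dim))
    ms_stop("no image geometry available; supply img_dim",
            "morphsal_input_error")
  ctr <- colMeans(rep$means)
  sdl <- stats::sd(rep$means[, dim])
  grid <- seq(ctr[dim] - 2 * sdl, ctr[dim] + 2 * sdl, length.out = n_grid)
  Xstar <- matrix(ctr, n_grid, rep$latent_dim, byrow = TRUE)
  Xstar[, dim] <- grid
  pred <- gplvm_predict_mean(rep, Xstar)
  sal <- apply(pred, 2, stats::sd)
  saliency_map(matrix(sal, nrow = img_dim[1]),
               source_tag = sprintf("gplvm-dim-%d", dim))
}

#' Estimate a foreground mask from an image stack
#'
#' Marks pixels whose across-specimen mean intensity differs from the
#' background median by more than `nmad` background MADs, then dilates the
#' mask by `dilate` pixels so that outline pixels touched only under pose
#' variation still count as foreground.
#'
#' @param images N x D matrix or list of images.
#' @param nmad MAD multiplier.
#' @param dilate Dilation radius in pixels.
#' @return Logical matrix (TRUE = foreground).
#' @export
foreground_mask <- function(images, nmad = 3, dilate = 2L) {
  Y <- if (is.matrix(images)) images else flatten_images(images)
  img_dim <- attr(Y, "img_dim")
  m <- colMeans(Y)
  med <- stats::median(m)
  madv <- max(stats::mad(m), 1e-6)
  fg <- abs(m - med) > nmad * madv
  if (is.null(img_dim)) return(fg)
  fg <- matrix(fg, nrow = img_dim[1])
  if (dilate > 0) fg <- dilate_mask(fg, as.integer(dilate))
  fg
}

#' Screen latent dimensions for technical artifacts
#'
#' For each of the top-ranked latent dimensions, projects its variability to
#' image space, runs the pixel-wise permutation significance test, and flags
#' the dimension as artifact-driven when too large a fraction of its
#' significant pixels falls outside the specimen foreground.  The retained
#' ("selected") dimensions are the highest-ranked unflagged ones.
#'
#' @param rep A `gplvm_fit`.
#' @param foreground_mask Logical matrix, TRUE on the specimen foreground.
#' @param top_k Number of top-ranked dimensions to screen.
#' @param out_frac_threshold Flag when the fraction of significant pixels
#'   outside the foreground exceeds this value.
#' @param n_sel Number of retained dimensions requested (default `top_k`).
#' @param keep List of dimension indices to retain unconditionally (manual
#'   override of the automated screen), or NULL.
#' @param k,n_resamples,threshold,seed Saliency-test parameters, see
#'   [pvalue_map()].
#' @return An object of class `dimension_screen`: a report data frame
#'   (dimension, rank, alpha, significant-pixel counts inside/outside the
#'   foreground, outside fraction, artifact flag), the saliency maps, the
#'   p-value maps and the `selected` dimension vector.
#' @export
screen_dimensions <- function(rep, foreground_mask, top_k = rep$latent_dim,
                              out_frac_threshold = 0.10, n_sel = top_k,
                              keep = NULL,
                              k = 5L, n_resamples = 1000L, threshold = 0.001,
                              seed = 1L) {
  if (top_k > rep$latent_dim)
    ms_stop("top_k exceeds the number of latent dimensions",
            "morphsal_input_error")
  rk <- rank_dimensions(rep)[seq_len(top_k)]
  fg <- as.logical(foreground_mask)
  maps <- list(); pmaps <- list()
  rows <- vector("list", top_k)
  for (i in seq_along(rk)) {
    d <- rk[i]
    sm <- project_dimension(rep, d)
    pm <- pvalue_map(sm, k = k, n_resamples = n_resamples,
                     threshold = threshold, seed = seed + i)
    sig <- as.logical(pm$mask)
    n_in <- sum(sig & fg); n_out <- sum(sig & !fg)
    frac_out <- if (n_in + n_out > 0) n_out / (n_in + n_out) else 0
    flag <- if (!is.null(keep)) !(d %in% keep) && frac_out > out_frac_threshold
            else frac_out > out_frac_threshold
    maps[[i]] <- sm; pmaps[[i]] <- pm
    rows[[i]] <- data.frame(dimension = d, rank = i,
                            alpha = rep$inv_length_scales[d],
                            n_sig_inside = n_in, n_sig_outside = n_out,
                            frac_outside = frac_out, artifact_flag = flag)
  }
  report <- do.call(rbind, rows)
  selected <- report$dimension[!report$artifact_flag]
  selected <- selected[seq_len(min(n_sel, length(selected)))]
  structure(list(report = report, maps = maps, pmaps = pmaps,
                 selected = selected),
            class = "dimension_screen")
}

#' @export
print.dimension_screen <- function(x, ...) {
  cat(sprintf("dimension_screen: %d screened, %d flagged, selected: %s\n",
              nrow(x$report), sum(x$report$artifact_flag),
              paste(x$selected, collapse = " ")))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Serialize a latent representation to CSV files
#'
#' Writes `means.csv` (posterior means), `covariances.csv` (posterior
#' variances) and `params.csv` (ARD weights, signal variance, noise
#' precision, bound) into a directory.
#'
#' @param fit A `gplvm_fit`.
#' @param directory Output directory.
#' @export
write_latent <- function(fit, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$means),
                   file.path(directory, "means.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$covariances),
                   file.path(directory, "covariances.csv"), row.names = FALSE)
  pr <- data.frame(name = c(paste0("alpha", seq_len(fit$latent_dim)),
                            "signal_variance", "noise_precision", "bound"),
                   value = c(fit$inv_length_scales, fit$signal_variance,
                             fit$noise_precision, fit$bound))
  utils::write.csv(pr, file.path(directory, "params.csv"), row.names = FALSE)
  invisible(directory)
}
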