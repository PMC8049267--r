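# One-vs-rest Gaussian process classification with ARD.
#
# Each of the C classes gets a binary GP classifier: logistic likelihood,
# zero-mean GP prior with squared-exponential ARD covariance
#   k(x, x') = sf2 * exp(-0.5 * sum_l alpha_l (x_l - x'_l)^2),
# latent posterior approximated by the Laplace approximation (Newton mode
# finding), and kernel hyperparameters {log sf2, log alpha} optimized by
# maximizing the approximate log marginal likelihood with its analytic
# gradient.  Binary predictive probabilities come from the probit-style
# moment-matched integral of the logistic over the latent Gaussian; the
# 1-of-C probabilities are the binary probabilities normalized across
# classes.  The ARD profile reports per-dimension alpha averaged over the C
# binary machines.

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

se_ard_kernel <- function(X1, X2, alpha, sf2) {
  d <- matrix(0, nrow(X1), nrow(X2))
  for (l in seq_len(ncol(X1)))
    d <- d + alpha[l] * outer(X1[, l], X2[, l], "-")^2
  sf2 * exp(-0.5 * d)
}

# n^2 x L matrix of per-dimension squared differences, shared across the C
# machines; lets kernel assembly and gradient contraction run as single
# matrix products
sq_diff_mat <- function(X) {
  n <- nrow(X)
  D2m <- matrix(0, n * n, ncol(X))
  for (l in seq_len(ncol(X)))
    D2m[, l] <- as.vector(outer(X[, l], X[, l], "-")^2)
  D2m
}

kernel_from_sq <- function(D2m, n, alpha, sf2) {
  matrix(sf2 * exp(-0.5 * as.vector(D2m %*% alpha)), n, n)
}

# Laplace approximation for binary GPC, logistic link, targets t in {0,1}.
# Returns the mode, the converged log marginal likelihood approximation and
# the pieces needed for gradients/prediction (Rasmussen-Williams style).
gpc_laplace <- function(K, t, max_newton = 50L, tol = 1e-8, f0 = NULL) {
  n <- length(t)
  f <- f0 %||% rep(0, n)
  obj_old <- -Inf
  for (it in seq_len(max_newton)) {
    pi_ <- sigmoid(f)
    Wd <- pmax(pi_ * (1 - pi_), 1e-12)
    sW <- sqrt(Wd)
    Bm <- diag(n) + (sW %o% sW) * K
    Lc <- chol(Bm)
    b <- Wd * f + (t - pi_)
    Kb <- K %*% b
    a <- as.vector(b - sW * backsolve(Lc, forwardsolve(t(Lc), sW * Kb)))
    f <- as.vector(K %*% a)
    loglik <- sum(t * f - softplus(f))
    obj <- -0.5 * sum(a * f) + loglik
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  pi_ <- sigmoid(f)
  Wd <- pmax(pi_ * (1 - pi_), 1e-12)
  sW <- sqrt(Wd)
  Bm <- diag(n) + (sW %o% sW) * K
  Lc <- chol(Bm)
  lml <- -0.5 * sum(a * f) + sum(t * f - softplus(f)) -
    sum(log(diag(Lc)))
  list(f = f, a = a, sW = sW, L = Lc, pi = pi_, lml = lml)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a one-vs-rest ARD Gaussian process classifier
#'
#' @param X_train N x L numeric feature matrix.
#' @param y_train Class labels (integer or factor); all classes present in
#'   `levels` must occur.
#' @param seed Integer seed (hyperparameter initialization jitter).
#' @param max_opt_iter L-BFGS-B iteration cap per binary machine.
#' @param levels Optional fixed class set (defaults to the sorted unique
#'   labels).
#' @return Object of class `gpc_fit` with per-class kernels and an
#'   `ard_profile` (per-dimension alpha averaged over the binary machines).
#' @export
fit_gpc <- function(X_train, y_train, seed = 1L, max_opt_iter = 15L,
                    levels = NULL) {
  X <- as.matrix(X_train)
  if (!all(is.finite(X)))
    ms_stop("features must be finite", "morphsal_input_error")
  labs <- as.vector(y_train)
  lv <- levels %||% sort(unique(labs))
  if (length(lv) < 2)
    ms_stop("need at least two classes", "morphsal_input_error")
  missing_cl <- setdiff(lv, unique(labs))
  if (length(missing_cl) > 0)
    ms_stop(paste0("class absent from training data: ",
                   paste(missing_cl, collapse = ", ")),
            "morphsal_input_error")
  set.seed(seed)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Ld <- ncol(Xs)
  D2 <- sq_diff_mat(Xs)
  machines <- vector("list", length(lv))
  alphas <- matrix(0, length(lv), Ld)
  for (ci in seq_along(lv)) {
    t01 <- as.numeric(labs == lv[ci])
    theta0 <- c(rep(log(1 / Ld), Ld), log(1)) +
      stats::rnorm(Ld + 1, 0, 0.01)
    cache <- new.env(parent = emptyenv())
    evalf <- function(th) {
      if (!is.null(cache$par) && identical(cache$par, th)) return(cache$res)
      res <- gpc_nlml_t(th, D2, t01)
      cache$par <- th; cache$res <- res
      res
    }
    opt <- stats::optim(theta0, function(th) evalf(th)$value,
                        function(th) evalf(th)$grad,
                        method = "L-BFGS-B",
                        lower = rep(-15, Ld + 1), upper = rep(6, Ld + 1),
                        control = list(maxit = as.integer(max_opt_iter)))
    alpha <- exp(opt$par[seq_len(Ld)])
    sf2 <- exp(opt$par[Ld + 1])
    K <- kernel_from_sq(D2, nrow(Xs), alpha, sf2) + diag(1e-6, nrow(Xs))
    la <- gpc_laplace(K, t01)
    machines[[ci]] <- list(alpha = alpha, sf2 = sf2, a = la$a, sW = la$sW,
                           L = la$L, lml = la$lml, dlp = t01 - la$pi)
    alphas[ci, ] <- alpha
  }
  ard <- colMeans(alphas)
  names(ard) <- colnames(X) %||% paste0("x", seq_len(Ld))
  structure(list(machines = machines, levels = lv, center = ctr,
                 scale = scl, X = Xs,
                 ard_profile = list(alpha = ard, per_class = alphas),
                 model_tag = "GPC"),
            class = "gpc_fit")
}

# marginal likelihood + gradient with the 0/1 targets threaded through
gpc_nlml_t <- function(theta, D2, t01) {
  Ld <- ncol(D2)
  alpha <- exp(theta[seq_len(Ld)])
  sf2 <- exp(theta[Ld + 1])
  n <- length(t01)
  K <- kernel_from_sq(D2, n, alpha, sf2) + diag(1e-6, n)
  la <- gpc_laplace(K, t01)
  f <- la$f; a <- la$a; sW <- la$sW; Lc <- la$L; pi_ <- la$pi
  Zm <- (sW %o% sW) * chol2inv(Lc)
  Cm <- forwardsolve(t(Lc), sW * K)
  dd <- diag(K) - colSums(Cm^2)
  d3 <- -pi_ * (1 - pi_) * (1 - 2 * pi_)
  s2 <- 0.5 * dd * d3
  dlp <- t01 - pi_
  # explicit + implicit chain terms contracted against each dK without
  # materializing dK per hyperparameter:
  #   s1_j  = sum(G * dK_j),          G  = 0.5 (a a' - Zm)
  #   s23_j = u' dK_j dlp,            u  = s2 - Zm K s2
  GK <- (0.5 * ((a %o% a) - Zm)) * K
  u <- s2 - as.vector(Zm %*% (K %*% s2))
  UDK <- (u %o% dlp) * K
  contr <- as.vector(crossprod(D2, as.vector(GK) + as.vector(UDK)))
  grads <- numeric(Ld + 1)
  grads[seq_len(Ld)] <- 0.5 * alpha * contr
  diagG <- 0.5 * (a^2 - diag(Zm))
  s1 <- sum(GK) - 1e-6 * sum(diagG)
  s23 <- sum(UDK) - 1e-6 * sum(u * dlp)
  grads[Ld + 1] <- -(s1 + s23)
  list(value = -la$lml, grad = grads)
}

#' Predict origin-class probabilities from a fitted GPC
#'
#' @param object A `gpc_fit`.
#' @param newdata N_test x L feature matrix.
#' @param ... Unused.
#' @return Object of class `classifier_result`: `posterior` (rows sum to 1),
#'   `predicted` (argmax labels) and `model_tag`.
#' @export
predict.gpc_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  C <- length(object$levels)
  pbin <- matrix(0, nrow(Xs), C)
  for (ci in seq_len(C)) {
    m <- object$machines[[ci]]
    Ks <- se_ard_kernel(Xs, object$X, m$alpha, m$sf2)
    fmean <- as.vector(Ks %*% m$a)
    Vp <- forwardsolve(t(m$L), t(Ks * rep(m$sW, each = nrow(Xs))))
    fvar <- pmax(m$sf2 - colSums(Vp^2), 1e-12)
    kappa <- 1 / sqrt(1 + pi * fvar / 8)   # moment-matched logistic integral
    pbin[, ci] <- sigmoid(kappa * fmean)
  }
  post <- pbin / rowSums(pbin)
  classifier_result(post, object$levels, "GPC")
}

classifier_result <- function(posterior, levels, tag) {
  colnames(posterior) <- as.character(levels)
  structure(list(posterior = posterior,
                 predicted = levels[max.col(posterior, ties.method = "first")],
                 model_tag = tag),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("classifier_result (%s): %d predictions over %d classes\n",
              x$model_tag, nrow(x$posterior), ncol(x$posterior)))
  invisible(x)
}
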