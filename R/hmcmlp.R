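# Bayesian multi-layer perceptron sampled with hybrid (Hamiltonian) Monte
# Carlo, with a hierarchical automatic-relevance-determination prior.
#
# Architecture: inputs -> tanh hidden layer -> softmax outputs, plus direct
# input->output connections.  Each input l owns two Gaussian prior scales:
# sigma_{l,1} for its input->hidden weights and sigma_{l,2} for its direct
# input->output weights.  The scales carry conjugate gamma hyperpriors on
# the precisions and are resampled by Gibbs steps between HMC updates of
# the weights (the classic alternating scheme for hierarchical Bayesian
# networks).  Predictions average the softmax over the retained posterior
# samples; the ARD profile reports posterior-mean scales.

mlp_unpack <- function(w, L, H, C) {
  i <- 0
  W1 <- matrix(w[i + seq_len(L * H)], L, H); i <- i + L * H
  b1 <- w[i + seq_len(H)]; i <- i + H
  W2 <- matrix(w[i + seq_len(H * C)], H, C); i <- i + H * C
  b2 <- w[i + seq_len(C)]; i <- i + C
  W3 <- matrix(w[i + seq_len(L * C)], L, C)
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# potential energy (negative log posterior up to constants) and gradient;
# yidx indexes the true-class entries of the logit matrix
mlp_potential <- function(w, Xs, Yoh, yidx, L, H, C, tau1, tau2, tau3, tau_b) {
  p <- mlp_unpack(w, L, H, C)
  A <- tanh(sweep(Xs %*% p$W1, 2, p$b1, "+"))
  Z <- sweep(A %*% p$W2 + Xs %*% p$W3, 2, p$b2, "+")
  rmax <- do.call(pmax, lapply(seq_len(C), function(j) Z[, j]))
  E <- exp(Z - rmax)
  sE <- rowSums(E)
  loglik <- sum(Z[yidx]) - sum(log(sE) + rmax)
  prior <- 0.5 * (sum(tau1 * rowSums(p$W1^2)) + tau2 * sum(p$W2^2) +
                    sum(tau3 * rowSums(p$W3^2)) +
                    tau_b * (sum(p$b1^2) + sum(p$b2^2)))
  U <- -loglik + prior
  dZ <- E / sE - Yoh
  dW2 <- crossprod(A, dZ) + tau2 * p$W2
  db2 <- colSums(dZ) + tau_b * p$b2
  dW3 <- crossprod(Xs, dZ) + tau3 * p$W3
  dA <- dZ %*% t(p$W2)
  dpre <- dA * (1 - A^2)
  dW1 <- crossprod(Xs, dpre) + tau1 * p$W1
  db1 <- colSums(dpre) + tau_b * p$b1
  list(U = U, grad = c(dW1, db1, dW2, db2, dW3), loglik = loglik)
}

#' Fit a Bayesian MLP classifier by hybrid Monte Carlo
#'
#' @param X_train N x L feature matrix.
#' @param Y_train Class labels, or an N x C one-hot (0/1) matrix.
#' @param hidden Number of hidden units (>= 1).
#' @param n_samples Number of MCMC iterations.
#' @param burn_in_frac Fraction of initial samples discarded.
#' @param seed Integer seed.
#' @param leapfrog Leapfrog steps per HMC update.
#' @param step_size Initial leapfrog step size (adapted during burn-in).
#' @param levels Optional fixed class set (when `Y_train` is a label
#'   vector).
#' @return Object of class `hmc_mlp_fit` with retained weight samples, the
#'   acceptance rate and an `ard_profile` carrying the posterior-mean prior
#'   scales `sigma1` (input to hidden), `sigma2` (input to output) and their
#'   summed-squares combination.
#' @export
fit_hmc_mlp <- function(X_train, Y_train, hidden = 20L, n_samples = 500L,
                        burn_in_frac = 0.25, seed = 1L, leapfrog = 10L,
                        step_size = 0.02, levels = NULL) {
  X <- as.matrix(X_train)
  if (hidden < 1) ms_stop("need hidden >= 1", "morphsal_input_error")
  if (is.matrix(Y_train) && ncol(Y_train) > 1) {
    if (!all(Y_train %in% c(0, 1)) || !all(rowSums(Y_train) == 1))
      ms_stop("Y_train matrix must be one-hot", "morphsal_input_error")
    lv <- levels %||% (seq_len(ncol(Y_train)) - 1L)
    labs <- lv[max.col(Y_train)]
    Yoh <- Y_train
  } else {
    labs <- as.vector(Y_train)
    lv <- levels %||% sort(unique(labs))
    missing_cl <- setdiff(lv, unique(labs))
    if (length(missing_cl) > 0)
      ms_stop(paste0("class absent from training data: ",
                     paste(missing_cl, collapse = ", ")),
              "morphsal_input_error")
    Yoh <- outer(labs, lv, "==") * 1
  }
  C <- length(lv); L <- ncol(X); H <- as.integer(hidden); N <- nrow(X)
  set.seed(seed)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  # gamma hyperprior on group precisions (shape a0, rate b0)
  a0 <- 0.5; b0 <- 0.05
  tau1 <- rep(1, L); tau3 <- rep(1, L); tau2 <- 1; tau_b <- 1
  w <- stats::rnorm(L * H + H + H * C + C + L * C, 0, 0.1)
  eps <- step_size
  n_burn <- floor(burn_in_frac * n_samples)
  keep_w <- matrix(0, n_samples - n_burn, length(w))
  keep_s1 <- matrix(0, n_samples - n_burn, L)
  keep_s2 <- matrix(0, n_samples - n_burn, L)
  keep_ll <- numeric(n_samples - n_burn)
  n_acc <- 0L

  yidx <- which(Yoh == 1)
  pot <- mlp_potential(w, Xs, Yoh, yidx, L, H, C, tau1, tau2, tau3, tau_b)
  for (it in seq_len(n_samples)) {
    # --- Gibbs update of the hierarchical ARD precisions ---
    p <- mlp_unpack(w, L, H, C)
    tau1 <- stats::rgamma(L, a0 + H / 2, rate = b0 + rowSums(p$W1^2) / 2)
    tau3 <- stats::rgamma(L, a0 + C / 2, rate = b0 + rowSums(p$W3^2) / 2)
    tau2 <- stats::rgamma(1, a0 + H * C / 2, rate = b0 + sum(p$W2^2) / 2)
    pot <- mlp_potential(w, Xs, Yoh, yidx, L, H, C, tau1, tau2, tau3, tau_b)
    if (!is.finite(pot$U))
      ms_stop(sprintf("divergent sampling: non-finite energy at iteration %d",
                      it), "morphsal_numeric_error")

    # --- HMC update of the weights ---
    mom <- stats::rnorm(length(w))
    H0 <- pot$U + 0.5 * sum(mom^2)
    wn <- w; g <- pot$grad
    mom <- mom - 0.5 * eps * g
    for (s in seq_len(leapfrog)) {
      wn <- wn + eps * mom
      pn <- mlp_potential(wn, Xs, Yoh, yidx, L, H, C, tau1, tau2, tau3, tau_b)
      if (!is.finite(pn$U)) break
      mom <- mom - (if (s < leapfrog) eps else 0.5 * eps) * pn$grad
    }
    accept <- is.finite(pn$U) && {
      H1 <- pn$U + 0.5 * sum(mom^2)
      log(stats::runif(1)) < H0 - H1
    }
    if (accept) { w <- wn; pot <- pn; n_acc <- n_acc + 1L }
    if (it <= n_burn) eps <- eps * if (accept) 1.05 else 0.85
    if (it > n_burn) {
      keep_w[it - n_burn, ] <- w
      keep_s1[it - n_burn, ] <- 1 / sqrt(tau1)
      keep_s2[it - n_burn, ] <- 1 / sqrt(tau3)
      keep_ll[it - n_burn] <- pot$loglik
    }
  }
  # split-chain stationarity check on the retained log likelihood, with a
  # batch-means standard error (retained samples are autocorrelated)
  nk <- length(keep_ll)
  if (nk >= 40) {
    bm <- vapply(split(keep_ll, rep(1:10, each = ceiling(nk / 10),
                                    length.out = nk)), mean, 0)
    se <- stats::sd(bm) * sqrt(2 / 5)
    if (is.finite(se) && se > 0 &&
        abs(mean(bm[1:5]) - mean(bm[6:10])) > 4 * se)
      warning("HMC chain halves differ; consider more samples/burn-in")
  }
  sigma1 <- apply(keep_s1, 2, stats::median)
  sigma2 <- apply(keep_s2, 2, stats::median)
  nms <- colnames(X) %||% paste0("x", seq_len(L))
  names(sigma1) <- names(sigma2) <- nms
  structure(list(samples = keep_w, levels = lv, center = ctr, scale = scl,
                 hidden = H, n_class = C, n_input = L,
                 acceptance = n_acc / n_samples,
                 ard_profile = list(sigma1 = sigma1, sigma2 = sigma2,
                                    combined = sqrt(sigma1^2 + sigma2^2)),
                 model_tag = "HMC-MLP"),
            class = "hmc_mlp_fit")
}

#' Predict class probabilities from a fitted HMC-MLP
#'
#' Posterior-averaged softmax over the retained weight samples.
#'
#' @param object An `hmc_mlp_fit`.
#' @param newdata N_test x L feature matrix.
#' @param thin Use every `thin`-th retained sample.
#' @param ... Unused.
#' @return A `classifier_result`.
#' @export
predict.hmc_mlp_fit <- function(object, newdata, thin = 1L, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  L <- object$n_input; H <- object$hidden; C <- object$n_class
  idx <- seq(1, nrow(object$samples), by = thin)
  post <- matrix(0, nrow(Xs), C)
  for (i in idx) {
    p <- mlp_unpack(object$samples[i, ], L, H, C)
    A <- tanh(sweep(Xs %*% p$W1, 2, p$b1, "+"))
    Z <- sweep(A %*% p$W2 + Xs %*% p$W3, 2, p$b2, "+")
    post <- post + softmax_rows(Z)
  }
  post <- post / length(idx)
  post <- post / rowSums(post)
  classifier_result(post, object$levels, "HMC-MLP")
}

#' @export
print.hmc_mlp_fit <- function(x, ...) {
  cat(sprintf(
    "hmc_mlp_fit: %d inputs, %d hidden, %d classes, %d retained samples (acc %.2f)\n",
    x$n_input, x$hidden, x$n_class, nrow(x$samples), x$acceptance))
  invisible(x)
}
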