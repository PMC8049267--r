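# Paired cross-testing and performance metrics: generalization accuracy,
# mutual information between posterior and labels (in bit), the exact
# two-sided McNemar test on discordant prediction counts, the majority-label
# baseline, and rank-frequency summaries of ARD relevances across
# reshuffles.

#' Build a paired cross-testing plan
#'
#' For each reshuffle, specimens are permuted and split into near-equal
#' stratified folds (round-robin over class-blocked order, so every class
#' appears in every training split where counts allow).  Every analysis
#' pipeline evaluated on the same plan sees the specimens in the same
#' order, making predictions exactly pairable.
#'
#' @param labels Specimen class labels.
#' @param n_folds Number of folds (default 10).
#' @param n_reshuffles Number of independent reshuffles (default 10).
#' @param seed Integer seed.
#' @return Object of class `crosstest_plan`: `folds` is an N x n_reshuffles
#'   integer matrix of fold assignments.
#' @export
make_plan <- function(labels, n_folds = 10L, n_reshuffles = 10L, seed = 1L) {
  N <- length(labels)
  if (n_folds > N)
    ms_stop("more folds than specimens", "morphsal_input_error")
  set.seed(seed)
  folds <- matrix(0L, N, n_reshuffles)
  for (r in seq_len(n_reshuffles)) {
    perm <- sample.int(N)
    ord <- perm[order(labels[perm])]   # class-blocked, shuffled within class
    fold_seq <- rep(seq_len(n_folds), length.out = N)
    folds[ord, r] <- fold_seq
  }
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 n_reshuffles = as.integer(n_reshuffles),
                 labels = labels, seed = as.integer(seed)),
            class = "crosstest_plan")
}

#' @export
print.crosstest_plan <- function(x, ...) {
  cat(sprintf("crosstest_plan: %d specimens, %d folds x %d reshuffles\n",
              nrow(x$folds), x$n_folds, x$n_reshuffles))
  invisible(x)
}

#' Write / read a cross-testing plan as CSV
#'
#' Long format: one row per (reshuffle, specimen) with its fold id.
#' @param plan A `crosstest_plan`.
#' @param path CSV path.
#' @export
write_plan <- function(plan, path) {
  long <- data.frame(
    reshuffle = rep(seq_len(plan$n_reshuffles), each = nrow(plan$folds)),
    specimen = rep(seq_len(nrow(plan$folds)), plan$n_reshuffles),
    fold = as.vector(plan$folds))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Generalization accuracy in percent
#'
#' @param predicted,true Aligned label vectors.
#' @return `100 * mean(predicted == true)`.
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) == 0 || length(predicted) != length(true))
    ms_stop("need nonempty aligned label vectors", "morphsal_input_error")
  100 * mean(predicted == true)
}

#' Mutual information between posterior and labels, in bit
#'
#' Approximates the mutual information between inputs and class labels by
#' averaging, over the evaluated samples, the Kullback-Leibler divergence
#' of the predicted posterior from the class marginal (taken as the
#' empirical class frequencies of the evaluated set).  Terms with zero
#' posterior mass contribute zero.  An input-independent predictor that
#' outputs the marginal scores exactly 0 bit; the maximum is log2(C).
#'
#' @param posterior N x C matrix of class probabilities (rows sum to 1);
#'   columns named by class, or aligned with the sorted unique labels.
#' @param true Label vector of length N.
#' @return Scalar, in bit.
#' @export
mutual_information <- function(posterior, true) {
  P <- as.matrix(posterior)
  lv <- colnames(P) %||% as.character(sort(unique(true)))
  if (max(abs(rowSums(P) - 1)) > 1e-6)
    ms_stop("posterior rows must sum to 1", "morphsal_input_error")
  marg <- vapply(lv, function(l) mean(true == l), 0)
  if (any(marg == 0 & colSums(P) > 0))
    ms_stop("class with predicted mass has zero marginal frequency",
            "morphsal_input_error")
  ratio <- sweep(P, 2, ifelse(marg > 0, marg, 1), "/")
  terms <- ifelse(P > 0, P * log2(ratio), 0)
  sum(terms) / nrow(P)
}

#' Exact McNemar test for paired classifiers
#'
#' Counts `n_a` (samples correct under `a`, wrong under `b`) and `n_b`
#' (wrong under `a`, correct under `b`) and computes the exact two-sided
#' binomial p-value `2 * P(X <= min(n_a, n_b))` with `X ~ Bin(n_a + n_b,
#' 0.5)`, capped at 1.  With no discordant pairs p = 1 (with a warning).
#'
#' @param pred_a,pred_b,true Aligned label vectors.
#' @return List with `n_a`, `n_b`, `p`.
#' @export
mcnemar <- function(pred_a, pred_b, true) {
  if (length(pred_a) != length(true) || length(pred_b) != length(true))
    ms_stop("prediction vectors must align with the truth",
            "morphsal_input_error")
  ca <- pred_a == true; cb <- pred_b == true
  n_a <- sum(ca & !cb); n_b <- sum(!ca & cb)
  if (n_a + n_b == 0) {
    warning("no discordant pairs; p = 1")
    return(list(n_a = n_a, n_b = n_b, p = 1))
  }
  p <- 2 * sum(stats::dbinom(0:min(n_a, n_b), n_a + n_b, 0.5))
  list(n_a = n_a, n_b = n_b, p = min(p, 1))
}

#' Truncated logit transform of a p-value
#'
#' Truncates to 0.99 and returns `log(p) - log(1 - p)`; p must be in
#' (0, 1] (an exact zero must be handled explicitly by the caller).
#'
#' @param p P-value(s) in (0, 1].
#' @return Transformed value(s).
#' @export
logit_truncate <- function(p) {
  if (any(p <= 0))
    ms_stop("p-value of 0 cannot be logit-transformed; handle explicitly",
            "morphsal_input_error")
  if (any(p > 1))
    ms_stop("p-values must not exceed 1", "morphsal_input_error")
  p <- pmin(p, 0.99)
  log(p) - log(1 - p)
}

#' Majority-label baseline predictor
#'
#' Predicts the modal training label for every sample, with the empirical
#' class frequencies as posterior (ties broken by class order).
#'
#' @param labels_train Training labels.
#' @return Object of class `majority_baseline`; `predict()` it on any
#'   number of samples.
#' @export
baseline_majority <- function(labels_train) {
  if (length(labels_train) == 0)
    ms_stop("empty training labels", "morphsal_input_error")
  lv <- sort(unique(labels_train))
  cnt <- vapply(lv, function(l) sum(labels_train == l), 0L)
  structure(list(levels = lv, modal = lv[which.max(cnt)],
                 freq = cnt / sum(cnt), model_tag = "majority"),
            class = "majority_baseline")
}

#' @export
predict.majority_baseline <- function(object, newdata, n = NULL, ...) {
  nn <- n %||% (if (is.matrix(newdata)) nrow(newdata) else length(newdata))
  post <- matrix(object$freq, nn, length(object$levels), byrow = TRUE)
  colnames(post) <- as.character(object$levels)
  structure(list(posterior = post,
                 predicted = rep(object$modal, nn),
                 model_tag = "majority"),
            class = "classifier_result")
}

#' Rank-occupancy frequencies of features across reshuffles
#'
#' For each rank position r = 1..top_ranks, tabulates how often each
#' feature occupies that rank when the relevance vectors of the individual
#' reshuffles are sorted in decreasing order.
#'
#' @param relevance_per_reshuffle List of equal-length relevance vectors.
#' @param top_ranks Number of leading rank positions summarized.
#' @return `top_ranks` x n_features matrix of relative frequencies; each
#'   row sums to 1.
#' @export
rank_frequencies <- function(relevance_per_reshuffle, top_ranks = 5L) {
  if (length(relevance_per_reshuffle) == 0)
    ms_stop("empty relevance list", "morphsal_input_error")
  lens <- vapply(relevance_per_reshuffle, length, 0L)
  if (length(unique(lens)) != 1)
    ms_stop("relevance vectors must have equal length", "morphsal_input_error")
  nf <- lens[1]
  nms <- names(relevance_per_reshuffle[[1]]) %||% paste0("f", seq_len(nf))
  freq <- matrix(0, top_ranks, nf, dimnames = list(paste0("rank", seq_len(top_ranks)), nms))
  for (rel in relevance_per_reshuffle) {
    ord <- order(-rel, seq_along(rel))
    for (r in seq_len(top_ranks))
      freq[r, ord[r]] <- freq[r, ord[r]] + 1
  }
  freq / length(relevance_per_reshuffle)
}

#' Frequency-weighted saliency map over leading rank positions
#'
#' Averages per-dimension saliency maps with weights given by how often
#' each dimension occupies the requested rank positions across reshuffles.
#'
#' @param maps Named list of [saliency_map()]s (or matrices), names matching
#'   the feature columns of `rank_freqs`.
#' @param rank_freqs Rank-frequency matrix from [rank_frequencies()].
#' @param ranks Rank positions to pool (default 1:2).
#' @return A [saliency_map()].
#' @export
weighted_saliency <- function(maps, rank_freqs, ranks = 1:2) {
  w <- colMeans(rank_freqs[ranks, , drop = FALSE])
  w <- w / sum(w)
  used <- names(w)[w > 0]
  missing_maps <- setdiff(used, names(maps))
  if (length(missing_maps) > 0)
    ms_stop(paste0("missing saliency map for weighted dimension(s): ",
                   paste(missing_maps, collapse = ", ")),
            "morphsal_input_error")
  acc <- 0
  for (d in used) acc <- acc + w[[d]] * sal_values(maps[[d]])
  saliency_map(acc, source_tag = paste0("weighted-ranks-",
                                        paste(ranks, collapse = "+")))
}

#' Run paired cross-testing of a classifier over a plan
#'
#' Fits the supplied classifier on the training folds and predicts the held
#' out fold, for every (reshuffle, fold) pair of the plan, returning
#' specimen-aligned predictions plus per-reshuffle metrics and ARD
#' relevance summaries.
#'
#' @param X N x L feature matrix (specimen order fixed by the plan).
#' @param labels Specimen labels.
#' @param plan A [make_plan()] object built on the same specimens.
#' @param classifier `"gpc"` or `"hmc_mlp"`.
#' @param seed Integer seed; fold-level fits derive their seeds from it.
#' @param ... Passed to the classifier fit function.
#' @return Object of class `crosstest_result`: `predicted` and `posterior`
#'   per reshuffle (specimen-aligned), `metrics` data frame (accuracy, MI,
#'   McNemar vs the majority baseline, raw and logit-truncated), and
#'   `relevance` (per-reshuffle ARD vectors averaged over folds).
#' @export
cross_test <- function(X, labels, plan, classifier = c("gpc", "hmc_mlp"),
                       seed = 1L, ...) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N != nrow(plan$folds))
    ms_stop("plan and features disagree on specimen count",
            "morphsal_input_error")
  lv <- sort(unique(labels))
  C <- length(lv)
  preds <- matrix(NA, N, plan$n_reshuffles)
  post <- array(NA_real_, c(N, C, plan$n_reshuffles))
  relevance <- vector("list", plan$n_reshuffles)
  metrics <- vector("list", plan$n_reshuffles)
  for (r in seq_len(plan$n_reshuffles)) {
    rel_folds <- list()
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(plan$folds[, r] == f)
      if (length(test_idx) == 0) next
      train_idx <- setdiff(seq_len(N), test_idx)
      fit <- if (classifier == "gpc") {
        fit_gpc(X[train_idx, , drop = FALSE], labels[train_idx],
                seed = seed + 1000L * r + f, levels = lv, ...)
      } else {
        fit_hmc_mlp(X[train_idx, , drop = FALSE], labels[train_idx],
                    seed = seed + 1000L * r + f, levels = lv, ...)
      }
      pr <- predict(fit, X[test_idx, , drop = FALSE])
      preds[test_idx, r] <- pr$predicted
      post[test_idx, , r] <- pr$posterior
      rel_folds[[f]] <- if (classifier == "gpc") fit$ard_profile$alpha
                        else fit$ard_profile$combined
    }
    relevance[[r]] <- Reduce(`+`, rel_folds) / length(rel_folds)
    base <- predict(baseline_majority(labels), NULL, n = N)
    mc <- mcnemar(preds[, r], base$predicted, labels)
    pp <- post[, , r]
    colnames(pp) <- as.character(lv)
    metrics[[r]] <- data.frame(
      reshuffle = r,
      acc = accuracy(preds[, r], labels),
      mi = mutual_information(pp, labels),
      mcnemar_p = mc$p,
      mcnemar_logit = if (mc$p > 0) logit_truncate(mc$p) else -Inf,
      n_a = mc$n_a, n_b = mc$n_b)
  }
  structure(list(predicted = preds, posterior = post,
                 metrics = do.call(rbind, metrics),
                 relevance = relevance, classifier = classifier,
                 levels = lv, plan = plan),
            class = "crosstest_result")
}

#' @export
print.crosstest_result <- function(x, ...) {
  cat(sprintf("crosstest_result (%s): mean acc %.1f%%, mean MI %.3f bit\n",
              x$classifier, mean(x$metrics$acc), mean(x$metrics$mi)))
  invisible(x)
}
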