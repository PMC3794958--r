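#' Confusion matrix and summary metrics
#'
#' Positive class is PiB(+). Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/n, all returned as fractions in \[0, 1\].
#'
#' @param predictions,labels vectors coercible to the [pib_levels()] factor,
#'   same length.
#' @return list with `confusion` (named counts TP, FN, TN, FP),
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predictions, labels) {
  if (!length(labels)) stop("empty input")
  pred <- as_pib_factor(predictions)
  y <- as_pib_factor(labels)
  if (length(pred) != length(y)) stop("predictions and labels differ in length")
  TP <- sum(pred == "PiB_positive" & y == "PiB_positive")
  FN <- sum(pred == "PiB_negative" & y == "PiB_positive")
  TN <- sum(pred == "PiB_negative" & y == "PiB_negative")
  FP <- sum(pred == "PiB_positive" & y == "PiB_negative")
  list(confusion = c(TP = TP, FN = FN, TN = TN, FP = FP),
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       accuracy = (TP + TN) / length(y))
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Utility for consistency checks against published sensitivity/specificity
#' figures: with known class sizes, the printed rates determine the integer
#' counts (TP = round(sens * n_pos), TN = round(spec * n_neg)).
#'
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @param n_pos,n_neg class sizes.
#' @return named counts c(TP, FN, TN, FP).
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  TP <- as.integer(round(sensitivity * n_pos))
  TN <- as.integer(round(specificity * n_neg))
  c(TP = TP, FN = as.integer(n_pos) - TP, TN = TN, FP = as.integer(n_neg) - TN)
}

#' Stratified cross-validation folds
#'
#' Assigns each subject to one of `k` folds, preserving class proportions:
#' within each class, fold sizes differ by at most one.
#'
#' @param labels class labels, see [pib_levels()].
#' @param k number of folds; `k = length(labels)` gives leave-one-out.
#' @param seed integer RNG seed.
#' @return integer fold assignment of length `length(labels)`.
#' @export
make_folds <- function(labels, k, seed) {
  y <- as_pib_factor(labels)
  n <- length(y)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  if (k == n) return(seq_len(n))   # leave-one-out
  folds <- integer(n)
  rng <- rng_stream(seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx[rng$sample_perm(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

# small deterministic RNG wrapper: isolates seed use from the global stream
rng_stream <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    sample_perm = function(n) with_state(sample.int(n)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    sample_int = function(n, size) with_state(sample.int(n, size))
  )
}

#' Stratified k-fold cross-validation of the PCA+LDA classifier
#'
#' Per fold: train on the other k-1 folds with [train_batch()], score the
#' held-out fold. Metrics and the ROC are computed from the pooled
#' out-of-fold predictions and decision scores.
#'
#' @param X subjects x features matrix.
#' @param labels see [pib_levels()].
#' @param k folds (default 10; `k = n` is leave-one-out).
#' @param seed fold-assignment seed.
#' @param variance_fraction PCA retained-variance threshold.
#' @param threshold LDA threshold rule.
#' @return An object of class `cv_result`: `predictions` (data.frame with
#'   subject_id, fold, score, predicted, label), `confusion`, `sensitivity`,
#'   `specificity`, `accuracy`, `roc`, `auc`, `folds`.
#' @export
run_cv <- function(X, labels, k = 10, seed = 1, variance_fraction = 0.70,
                   threshold = "midpoint") {
  y <- as_pib_factor(labels)
  folds <- make_folds(y, k, seed)
  score <- numeric(length(y))
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || any(table(y[tr]) < 2))
      stop(sprintf("fold %d leaves a training partition without both classes", f))
    state <- train_batch(X[tr, , drop = FALSE], y[tr], variance_fraction, threshold)
    out <- predict_subject(state, X[!tr, , drop = FALSE])
    score[!tr] <- out$score
    pred[!tr] <- as.character(out$label)
  }
  cm <- confusion_metrics(pred, y)
  roc <- roc_auc(score, y)
  structure(c(list(predictions = data.frame(
      subject_id = rownames(X) %||% seq_along(y), fold = folds,
      score = score, predicted = pred, label = as.character(y)),
      folds = folds, roc = roc$roc, auc = roc$auc), cm),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: n = %d, accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f\n",
              nrow(x$predictions), 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity, x$auc))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' AUC is the Mann-Whitney pair-win fraction (ties count 1/2), computed via
#' midranks; the ROC polyline comes from sweeping the score threshold.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels see [pib_levels()].
#' @return list with `roc` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_pib_factor(labels)
  npos <- sum(y == "PiB_positive"); nneg <- sum(y == "PiB_negative")
  if (npos == 0 || nneg == 0) stop("both classes required for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == "PiB_positive"]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == "PiB_positive") / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == "PiB_negative") / nneg, 0)
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Incremental learning curve
#'
#' Emulates steady data accrual: for each of `n_orders` random orderings of
#' the training subjects, batches of `batch_size` are absorbed via
#' [update_incremental()], and after every batch the full test set is
#' scored. Reported accuracies are averaged over orderings at each
#' training-set size. If an early state is not yet trainable (a class with
#' < 2 subjects), its grid point is recorded as NA for that ordering.
#'
#' @param X_train,y_train training features/labels.
#' @param X_test,y_test held-out features/labels scored at every step.
#' @param n_orders number of random orderings (default 500).
#' @param batch_size subjects per increment (default 10).
#' @param seed RNG seed for the orderings.
#' @param variance_fraction,threshold classifier settings.
#' @return An object of class `learning_curve`: `sizes`, `mean_accuracy`,
#'   `accuracy` (orders x sizes matrix), `n_orders`, `batch_size`.
#' @export
learning_curve <- function(X_train, y_train, X_test, y_test,
                           n_orders = 500, batch_size = 10, seed = 1,
                           variance_fraction = 0.70, threshold = "midpoint") {
  if (batch_size < 1 || n_orders < 1) stop("batch_size and n_orders must be >= 1")
  y_train <- as_pib_factor(y_train)
  n <- length(y_train)
  sizes <- as.integer(unique(c(seq.int(min(batch_size, n), n, by = batch_size), n)))
  rng <- rng_stream(seed)
  acc <- matrix(NA_real_, n_orders, length(sizes))
  for (o in seq_len(n_orders)) {
    ord <- rng$sample_perm(n)
    state <- new_classifier_state(variance_fraction, threshold)
    pos <- 0L
    for (si in seq_along(sizes)) {
      take <- ord[(pos + 1L):sizes[si]]
      pos <- sizes[si]
      state <- update_incremental(state, X_train[take, , drop = FALSE], y_train[take])
      if (!is.null(state$lda)) {
        out <- predict_subject(state, X_test)
        acc[o, si] <- mean(out$label == as_pib_factor(y_test))
      }
    }
  }
  structure(list(sizes = sizes, mean_accuracy = colMeans(acc, na.rm = TRUE),
                 accuracy = acc, n_orders = n_orders, batch_size = batch_size),
            class = "learning_curve")
}

#' Permutation test of cross-validated classification accuracy
#'
#' Null distribution of the k-fold CV accuracy under random relabelling:
#' for each permutation the *training* labels are permuted before training,
#' while held-out folds are always scored against the true labels. The fold
#' assignment is fixed (from the true labels) across permutations, and
#' since PCA is label-independent the per-fold PCA projection is computed
#' once, with only the LDA discriminant refit per permutation; the
#' statistic is identical to rerunning the full CV with permuted training
#' labels. p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param X subjects x features matrix.
#' @param labels true labels, see [pib_levels()].
#' @param n_perm number of permutations (>= 1).
#' @param seed seed driving folds and permutations.
#' @param k CV folds.
#' @param variance_fraction,threshold classifier settings.
#' @return An object of class `permutation_result`: `observed`, `null`
#'   (length n_perm), `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(X, labels, n_perm = 10000, seed = 1, k = 10,
                             variance_fraction = 0.70, threshold = "midpoint") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  y <- as_pib_factor(labels)
  n <- length(y)
  folds <- make_folds(y, k, seed)
  # per-fold PCA projections are label-free; precompute them
  fold_data <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    pca <- fit_pca(X[tr, , drop = FALSE], variance_fraction)
    list(test_idx = which(!tr), train_idx = which(tr),
         Z_train = pca_project(pca, X[tr, , drop = FALSE]),
         Z_test = pca_project(pca, X[!tr, , drop = FALSE]))
  })
  cv_accuracy <- function(y_train_full) {
    pred_pos <- logical(n)
    for (fd in fold_data) {
      ytr <- y_train_full[fd$train_idx]
      if (any(table(ytr) < 2)) return(NA_real_)
      lda <- fit_lda(fd$Z_train, ytr, threshold)
      pred_pos[fd$test_idx] <- lda_scores(lda, fd$Z_test) >= 0
    }
    mean(pred_pos == (y == "PiB_positive"))
  }
  observed <- cv_accuracy(y)
  rng <- rng_stream(seed + 1L)
  null <- vapply(seq_len(n_perm), function(i) cv_accuracy(y[rng$sample_perm(n)]),
                 numeric(1))
  dropped <- sum(is.na(null))
  if (dropped) {
    warning(sprintf("%d permutations produced a single-class training fold and scored as chance", dropped))
    null[is.na(null)] <- 0.5
  }
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = n_perm, seed = seed, k = k),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed accuracy %.2f%%, p = %.4g (%d permutations)\n",
              100 * x$observed, x$p_value, x$n_perm))
  invisible(x)
}
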