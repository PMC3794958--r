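#' Class labels used by the classifier
#'
#' The positive class is amyloid-positive (`PiB_positive`) throughout: it is
#' the class whose detection the sensitivity figures refer to.
#'
#' @return factor levels, negative first.
#' @export
pib_levels <- function() c("PiB_negative", "PiB_positive")

as_pib_factor <- function(labels) {
  f <- factor(as.character(labels), levels = pib_levels())
  if (any(is.na(f)))
    stop("labels must be 'PiB_negative'/'PiB_positive'")
  f
}

#' Fit a PCA model retaining a fraction of total variance
#'
#' Principal component analysis of the feature matrix, retaining
#' `d = min{k : cumvar(k) >= variance_fraction}` components. PCA is the
#' dimensionality-reduction step that makes LDA well-posed when subjects are
#' far fewer than spectral coefficients (n << p): the pooled scatter is
#' generically invertible in the retained subspace.
#'
#' @param X subjects x features matrix (>= 2 rows).
#' @param variance_fraction in (0, 1]; default 0.70.
#' @return An object of class `pca_model`: `center`, `components` (p x d,
#'   orthonormal columns), `variances` (all positive eigenvalues,
#'   non-increasing), `d`.
#' @export
fit_pca <- function(X, variance_fraction = 0.70) {
  if (nrow(X) < 2) stop("PCA needs at least 2 subjects")
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  n <- nrow(X)
  ctr <- colMeans(X)
  Q <- crossprod(X)
  fit_pca_stats(n, ctr, Q, variance_fraction)
}

# PCA from sufficient statistics: n, mean vector, raw cross-product sum(x x^T)
fit_pca_stats <- function(n, ctr, Q, variance_fraction) {
  C <- (Q - n * tcrossprod(ctr)) / (n - 1)
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  tot <- sum(pmax(eig$values, 0))
  if (tot <= 0) stop("zero total variance; PCA undefined")
  pos <- eig$values > max(eig$values) * 1e-10
  vars <- eig$values[pos]
  comps <- eig$vectors[, pos, drop = FALSE]
  cumfrac <- cumsum(vars) / tot
  d <- which(cumfrac >= variance_fraction - 1e-9)[1]
  if (is.na(d)) d <- length(vars)
  comps <- comps[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (k in seq_len(d)) {
    i <- which.max(abs(comps[, k]))
    if (comps[i, k] < 0) comps[, k] <- -comps[, k]
  }
  structure(list(center = ctr, components = comps,
                 variances = vars[seq_len(d)], all_variances = vars, d = d),
            class = "pca_model")
}

#' Project features into a PCA subspace
#' @param pca a [fit_pca()] model.
#' @param X matrix (or single feature vector).
#' @return n x d matrix of reduced coordinates.
#' @export
pca_project <- function(pca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(X, 2, pca$center) %*% pca$components
}

#' Fit a two-class linear discriminant in a reduced space
#'
#' Fisher discriminant axis w proportional to Sw^-1 (mu_pos - mu_neg),
#' normalised to unit length, with decision threshold c at the midpoint of
#' the projected class means (priors ignored; `threshold = "prior"` shifts
#' the cut by the log prior odds under the equal-covariance Gaussian model).
#' Scores are w'z - c; ties (score exactly 0) classify as positive,
#' consistent with a screening posture that favours sensitivity.
#'
#' @param Z subjects x d reduced feature matrix.
#' @param labels vector coercible via [pib_levels()]; both classes with >= 2
#'   subjects each.
#' @param threshold `"midpoint"` (default) or `"prior"`.
#' @return An object of class `lda_model`: `w` (unit), `c`, `means` (2 x d),
#'   `Sw` (pooled within-class scatter), `n_by_class`.
#' @export
fit_lda <- function(Z, labels, threshold = c("midpoint", "prior")) {
  threshold <- match.arg(threshold)
  y <- as_pib_factor(labels)
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1)
  cnt <- table(y)
  if (any(cnt < 2)) stop("each class needs >= 2 subjects for LDA")
  stats_by_class <- lapply(pib_levels(), function(lv) {
    Zc <- Z[y == lv, , drop = FALSE]
    list(n = nrow(Zc), mean = colMeans(Zc),
         scatter = crossprod(sweep(Zc, 2, colMeans(Zc))))
  })
  fit_lda_stats(stats_by_class, threshold)
}

# LDA from per-class stats: list of list(n, mean, scatter) for (neg, pos)
fit_lda_stats <- function(stats_by_class, threshold = "midpoint") {
  neg <- stats_by_class[[1]]; pos <- stats_by_class[[2]]
  Sw <- neg$scatter + pos$scatter
  dmu <- pos$mean - neg$mean
  a <- tryCatch(solve(Sw, dmu), error = function(e)
    stop("singular pooled scatter; reduce the PCA dimension (lower variance_fraction)"))
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) stop("identical class means; LDA axis undefined")
  w <- a / nrm
  cmid <- sum(w * (pos$mean + neg$mean)) / 2
  c_ <- if (threshold == "midpoint") cmid else {
    # equal-covariance Gaussian cut with empirical priors, on the unit axis
    n <- neg$n + pos$n
    Sw_cov <- Sw / (n - 2)
    cmid - log(pos$n / neg$n) * as.numeric(t(w) %*% Sw_cov %*% w) /
      sum(w * dmu)
  }
  structure(list(w = w, c = c_, threshold = threshold,
                 means = rbind(PiB_negative = neg$mean, PiB_positive = pos$mean),
                 Sw = Sw, n_by_class = c(PiB_negative = neg$n, PiB_positive = pos$n)),
            class = "lda_model")
}

lda_scores <- function(lda, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = 1)
  as.numeric(Z %*% lda$w) - lda$c
}

#' Create an empty classifier state
#'
#' Initialises the sufficient-statistics accumulators (per-class counts,
#' feature sums, and raw cross-product matrices) from which PCA and LDA are
#' re-derived after every update. Because the accumulators are exact, a
#' state that has absorbed batches B1..Bm is prediction-equivalent to batch
#' training on their union — the central incremental-learning contract.
#'
#' @param variance_fraction PCA retained-variance threshold (default 0.70).
#' @param threshold LDA threshold rule, see [fit_lda()].
#' @return An object of class `classifier_state`.
#' @export
new_classifier_state <- function(variance_fraction = 0.70,
                                 threshold = "midpoint") {
  structure(list(p = NULL, variance_fraction = variance_fraction,
                 threshold = threshold,
                 n = c(PiB_negative = 0L, PiB_positive = 0L),
                 s = NULL, Q = NULL,   # per-class sums / raw cross-products
                 pca = NULL, lda = NULL,
                 feature_names = NULL,
                 log = character(0)),
            class = "classifier_state")
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf("classifier_state: %d + %d subjects seen, p = %s, PCA d = %s\n",
              x$n[1], x$n[2], x$p %||% "?",
              if (is.null(x$pca)) "untrained" else x$pca$d))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Absorb a batch of labelled subjects and refit the classifier
#'
#' Adds the batch to the exact sufficient statistics, then re-derives the
#' PCA subspace from the accumulated total scatter and refits the LDA
#' discriminant (class means and pooled within-class scatter projected into
#' the new subspace). The refit happens once both classes have >= 2
#' subjects; before that the state accumulates but stays untrained.
#'
#' @param state a [new_classifier_state()] (possibly already holding data).
#' @param X batch feature matrix (subjects x features).
#' @param labels batch labels, see [pib_levels()].
#' @return the updated `classifier_state`.
#' @export
update_incremental <- function(state, X, labels) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) == 0) stop("empty batch")
  y <- as_pib_factor(labels)
  if (length(y) != nrow(X)) stop("labels length does not match batch size")
  if (is.null(state$p)) {
    state$p <- ncol(X)
    state$feature_names <- colnames(X)
    state$s <- list(PiB_negative = numeric(state$p), PiB_positive = numeric(state$p))
    state$Q <- list(PiB_negative = matrix(0, state$p, state$p),
                    PiB_positive = matrix(0, state$p, state$p))
  }
  if (ncol(X) != state$p)
    stop(sprintf("feature length %d does not match state's %d", ncol(X), state$p))
  for (lv in pib_levels()) {
    Xc <- X[y == lv, , drop = FALSE]
    if (nrow(Xc)) {
      state$n[lv] <- state$n[lv] + nrow(Xc)
      state$s[[lv]] <- state$s[[lv]] + colSums(Xc)
      state$Q[[lv]] <- state$Q[[lv]] + crossprod(Xc)
    }
  }
  state$log <- c(state$log,
                 sprintf("absorbed batch of %d (now %d neg / %d pos)",
                         nrow(X), state$n[1], state$n[2]))
  refit_state(state)
}

refit_state <- function(state) {
  if (any(state$n < 2L)) return(state)   # not yet trainable
  ntot <- sum(state$n)
  ctr <- (state$s[[1]] + state$s[[2]]) / ntot
  Qtot <- state$Q[[1]] + state$Q[[2]]
  state$pca <- fit_pca_stats(ntot, ctr, Qtot, state$variance_fraction)
  P <- state$pca$components
  cls <- lapply(pib_levels(), function(lv) {
    n_c <- as.numeric(state$n[lv])
    m_c <- state$s[[lv]] / n_c
    # within-class scatter in feature space, projected: P' (Q_c - n m m') P
    Sc <- crossprod(P, (state$Q[[lv]] - n_c * tcrossprod(m_c)) %*% P)
    list(n = n_c, mean = as.numeric(crossprod(P, m_c - ctr)),
         scatter = (Sc + t(Sc)) / 2)
  })
  state$lda <- fit_lda_stats(cls, state$threshold)
  state
}

#' Train a classifier on a full batch
#'
#' Equivalent to absorbing the whole training set into an empty state in a
#' single [update_incremental()] call (which is exactly how it is
#' implemented, so incremental and batch training share one code path).
#'
#' @param X subjects x features matrix.
#' @param labels see [pib_levels()]; both classes must be present.
#' @param variance_fraction PCA retained-variance threshold.
#' @param threshold LDA threshold rule.
#' @return a trained `classifier_state`.
#' @export
train_batch <- function(X, labels, variance_fraction = 0.70,
                        threshold = "midpoint") {
  state <- update_incremental(
    new_classifier_state(variance_fraction, threshold), X, labels)
  if (is.null(state$lda))
    stop("training set must contain >= 2 subjects of each class")
  state
}

#' Classify subjects with a trained state
#'
#' Scores are w'(P'(x - center)) - c; a subject is labelled positive iff its
#' score is >= 0 (ties go to the positive class).
#'
#' @param state a trained `classifier_state`.
#' @param X feature matrix or single feature vector.
#' @return list with `label` (factor) and `score` (numeric).
#' @export
predict_subject <- function(state, X) {
  if (is.null(state$pca) || is.null(state$lda))
    stop("classifier state is untrained")
  Z <- pca_project(state$pca, X)
  score <- lda_scores(state$lda, Z)
  label <- factor(ifelse(score >= 0, "PiB_positive", "PiB_negative"),
                  levels = pib_levels())
  list(label = label, score = score)
}

#' Serialize / restore a classifier state as JSON
#'
#' Version-tagged lossless round trip of the sufficient statistics and
#' configuration; the PCA/LDA models are re-derived on load.
#'
#' @param state a `classifier_state`.
#' @param path JSON path.
#' @return `path` invisibly (writer); `classifier_state` (reader).
#' @export
write_classifier <- function(state, path) {
  payload <- list(format = "subshape_classifier", version = 1L,
                  p = state$p, variance_fraction = state$variance_fraction,
                  threshold = state$threshold,
                  n = as.list(state$n),
                  s = state$s,
                  Q = lapply(state$Q, function(m) as.numeric(m)),
                  feature_names = state$feature_names,
                  log = state$log)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "subshape_classifier"))
    stop("not a serialized classifier state: ", path)
  state <- new_classifier_state(pl$variance_fraction, pl$threshold)
  state$p <- pl$p
  state$n <- c(PiB_negative = as.integer(pl$n$PiB_negative),
               PiB_positive = as.integer(pl$n$PiB_positive))
  state$s <- list(PiB_negative = pl$s$PiB_negative,
                  PiB_positive = pl$s$PiB_positive)
  state$Q <- list(PiB_negative = matrix(pl$Q$PiB_negative, pl$p, pl$p),
                  PiB_positive = matrix(pl$Q$PiB_positive, pl$p, pl$p))
  state$feature_names <- pl$feature_names
  state$log <- pl$log
  refit_state(state)
}
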