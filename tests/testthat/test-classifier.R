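test_that("PCA keeps the minimal component count reaching the variance target", {
  # ten orthogonal directions of exactly equal variance: 70% needs 7
  X10 <- rbind(diag(10), -diag(10))
  pca <- fit_pca(X10, 0.70)
  expect_identical(pca$d, 7L)
  expect_lt(max(abs(crossprod(pca$components) - diag(7))), 1e-8)
  expect_true(all(diff(pca$variances) <= 1e-12))

  # data varying along a single direction
  set.seed(1)
  t_ <- rnorm(20)
  dir <- c(3, 4, 0) / 5
  X1 <- outer(t_, dir)
  expect_identical(fit_pca(X1, 0.70)$d, 1L)

  # full variance keeps the rank of the centered data
  set.seed(2)
  Xr <- matrix(rnorm(6 * 10), 6, 10)   # rank 5 after centering
  expect_identical(fit_pca(Xr, 1.0)$d, 5L)

  expect_error(fit_pca(matrix(1, 5, 3), 0.7), "zero total variance")
  expect_error(fit_pca(X10[1, , drop = FALSE], 0.7), "at least 2")
})

test_that("projections are mean-centered and preserve the variance target", {
  set.seed(3)
  X <- matrix(rnorm(40 * 12), 40)
  pca <- fit_pca(X, 0.70)
  Z <- pca_project(pca, X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_gte(sum(apply(Z, 2, var)) / sum(apply(X, 2, var)), 0.70)
})

test_that("LDA axis matches the closed-form scatter solution and MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(4)
  for (rep in 1:5) {
    prob <- gaussian_problem(25, p = 4, delta = 2.5, seed = rep)
    lda <- fit_lda(prob$X, prob$y)
    # closed form: Sw^-1 (mu+ - mu-)
    pos <- prob$X[prob$y == "PiB_positive", ]; neg <- prob$X[prob$y == "PiB_negative", ]
    Sw <- crossprod(sweep(pos, 2, colMeans(pos))) + crossprod(sweep(neg, 2, colMeans(neg)))
    wref <- solve(Sw, colMeans(pos) - colMeans(neg))
    expect_gte(sum(lda$w * wref) / sqrt(sum(wref^2)), 0.9999)
    # MASS as an independent oracle for the direction
    mfit <- MASS::lda(prob$X, grouping = factor(prob$y, levels = pib_levels()))
    wm <- as.numeric(mfit$scaling[, 1])
    expect_gte(abs(sum(lda$w * wm)) / sqrt(sum(wm^2)), 0.9999)
  }
})

test_that("LDA separates 1-D clusters and is antisymmetric under label swap", {
  Z <- matrix(c(-3, -2.5, -2.8, 2.1, 2.9, 2.4), ncol = 1)
  y <- rep(pib_levels(), each = 3)
  lda <- fit_lda(Z, y)
  pred <- ifelse(subshape:::lda_scores(lda, Z) >= 0, pib_levels()[2], pib_levels()[1])
  expect_identical(pred, y)

  swapped <- rep(rev(pib_levels()), each = 3)
  lda2 <- fit_lda(Z, swapped)
  expect_equal(subshape:::lda_scores(lda2, Z),
               -subshape:::lda_scores(lda, Z), tolerance = 1e-12)
  expect_error(fit_lda(Z, rep(pib_levels(), c(1, 5))), ">= 2")
})

test_that("batch training survives n << p and scores planted separations", {
  coh <- fix_cohort(seed = 31)
  geom <- fix_geometry()
  X <- build_feature_matrix(coh, geom$bases, "combined", N_c = 15)
  state <- train_batch(X, coh$labels)
  pred <- predict_subject(state, X)
  expect_gte(mean(pred$label == coh$labels), 0.95)

  # 60 x 280 with pure noise: PCA absorbs the singularity
  set.seed(5)
  Xbig <- matrix(rnorm(60 * 280), 60)
  ybig <- rep(pib_levels(), each = 30)
  expect_s3_class(train_batch(Xbig, ybig), "classifier_state")

  # permuted labels stay far from perfect training separation
  set.seed(6)
  accs <- vapply(1:10, function(i) {
    st <- train_batch(X, sample(coh$labels))
    mean(predict_subject(st, X)$label == coh$labels)
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.9)
})

test_that("incremental updates are prediction-equivalent to batch training", {
  coh <- fix_cohort(seed = 32)
  geom <- fix_geometry()
  X <- build_feature_matrix(coh, geom$bases, "combined", N_c = 15)
  y <- coh$labels
  tr <- 1:50; te <- 51:68

  batch <- train_batch(X[tr, ], y[tr])
  single <- update_incremental(new_classifier_state(), X[tr, ], y[tr])
  expect_identical(predict_subject(single, X[te, ])$label,
                   predict_subject(batch, X[te, ])$label)

  # batches of 10 until exhaustion
  inc <- new_classifier_state()
  for (i in seq(1, 50, by = 10)) {
    inc <- update_incremental(inc, X[i:(i + 9), ], y[i:(i + 9)])
  }
  expect_identical(predict_subject(inc, X[te, ])$label,
                   predict_subject(batch, X[te, ])$label)
  expect_lt(max(abs(predict_subject(inc, X[te, ])$score -
                    predict_subject(batch, X[te, ])$score)), 1e-8)

  # accumulators reproduce batch mean and scatter
  expect_equal((inc$s[[1]] + inc$s[[2]]) / sum(inc$n), colMeans(X[tr, ]),
               tolerance = 1e-8)
  Qb <- crossprod(X[tr, ])
  expect_equal(inc$Q[[1]] + inc$Q[[2]], Qb, tolerance = 1e-8)

  expect_error(update_incremental(inc, X[, 1:10], y), "does not match")
  expect_error(update_incremental(inc, X[0, , drop = FALSE], y[0]), "empty")
})

test_that("prediction follows the midpoint threshold with ties going positive", {
  # symmetric 1-D problem whose projected class means have midpoint exactly 2
  X <- matrix(c(-1, 1, 3, 5), ncol = 1)
  y <- rep(pib_levels(), each = 2)
  st <- train_batch(X, y, variance_fraction = 1)
  at_mid <- predict_subject(st, matrix(2, 1, 1))
  expect_identical(as.character(at_mid$label), "PiB_positive")
  expect_identical(at_mid$score, 0)
  # feature at the positive-class training mean is positive
  expect_identical(as.character(predict_subject(st, matrix(4, 1, 1))$label),
                   "PiB_positive")
  expect_identical(as.character(predict_subject(st, matrix(0, 1, 1))$label),
                   "PiB_negative")
  expect_error(predict_subject(new_classifier_state(), X), "untrained")
})

test_that("labels agree with an independent closed-form LDA oracle on held-out data", {
  skip_if_not_installed("MASS")
  prob <- gaussian_problem(40, p = 6, delta = 2, seed = 7)
  st <- train_batch(prob$X, prob$y, variance_fraction = 1)
  set.seed(8)
  Xtest <- matrix(rnorm(100 * 6, mean = 1), 100)
  ours <- predict_subject(st, Xtest)$label
  mfit <- MASS::lda(prob$X, grouping = factor(prob$y, levels = pib_levels()),
                    prior = c(0.5, 0.5))
  theirs <- predict(mfit, Xtest)$class
  expect_identical(as.character(ours), as.character(theirs))
})

test_that("decision scores are invariant to a constant feature offset", {
  prob <- gaussian_problem(20, p = 5, delta = 2, seed = 9)
  shift <- rep(13.7, 5)
  st1 <- train_batch(prob$X, prob$y)
  st2 <- train_batch(sweep(prob$X, 2, shift, `+`), prob$y)
  s1 <- predict_subject(st1, prob$X[1:10, ])$score
  s2 <- predict_subject(st2, sweep(prob$X[1:10, , drop = FALSE], 2, shift, `+`))$score
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("classifier states serialize losslessly through JSON", {
  prob <- gaussian_problem(15, p = 4, delta = 2, seed = 10)
  st <- train_batch(prob$X, prob$y)
  path <- tempfile(fileext = ".json")
  write_classifier(st, path)
  st2 <- read_classifier(path)
  expect_identical(predict_subject(st2, prob$X)$label,
                   predict_subject(st, prob$X)$label)
  expect_equal(predict_subject(st2, prob$X)$score,
               predict_subject(st, prob$X)$score, tolerance = 1e-12)
})
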