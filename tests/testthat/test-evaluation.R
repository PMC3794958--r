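test_that("confusion metrics follow the standard definitions", {
  y <- rep(pib_levels(), c(3, 2))
  cm <- confusion_metrics(y, y)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_identical(unname(cm$confusion), c(2L, 0L, 3L, 0L))

  pred <- c("PiB_positive", "PiB_negative", "PiB_negative",
            "PiB_positive", "PiB_negative")
  cm2 <- confusion_metrics(pred, y)
  expect_identical(unname(cm2$confusion["TP"]), 1L)
  expect_identical(unname(cm2$confusion["FP"]), 1L)
  expect_equal(cm2$accuracy, 3 / 5)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
  expect_error(confusion_metrics(pred, y[1:3]), "length")
})

test_that("stratified folds partition each class almost evenly", {
  y <- rep(pib_levels(), c(45, 23))
  folds <- make_folds(y, 10, seed = 2)
  expect_identical(sort(unique(folds)), 1:10)
  for (lv in pib_levels()) {
    sizes <- table(folds[y == lv])
    expect_lte(diff(range(sizes)), 1)
  }
  # leave-one-out assigns every subject its own fold
  loo <- make_folds(y, length(y), seed = 2)
  expect_identical(sort(loo), seq_along(y))
  expect_error(make_folds(y, 1, 1), "k must be")
})

test_that("cross-validation tests every subject exactly once and scores planted effects", {
  coh <- fix_cohort(seed = 41)
  X <- build_feature_matrix(coh, fix_geometry()$bases, "combined", N_c = 15)
  cv <- run_cv(X, coh$labels, k = 10, seed = 3)
  expect_identical(nrow(cv$predictions), 68L)
  expect_identical(sort(unique(cv$folds)), 1:10)
  expect_gte(cv$accuracy, 0.85)
  expect_equal(sum(cv$confusion), 68)
  # metrics recomputable from the stored predictions
  cm <- confusion_metrics(cv$predictions$predicted, cv$predictions$label)
  expect_equal(cm$accuracy, cv$accuracy)
  # leave-one-out agrees with 10-fold within 5 points
  loo <- run_cv(X, coh$labels, k = 68, seed = 3)
  expect_lte(abs(loo$accuracy - cv$accuracy), 0.05)
})

test_that("AUC equals the Mann-Whitney pair-win fraction", {
  labs <- c("PiB_negative", "PiB_negative", "PiB_positive", "PiB_positive")
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), labs)
  expect_equal(r$auc, 0.75)   # 3 of 4 pos-neg pairs correctly ordered
  expect_equal(roc_auc(c(-1, -2, 5, 9), labs)$auc, 1.0)
  expect_equal(utils::tail(r$roc$tpr, 1), 1)
  expect_equal(utils::tail(r$roc$fpr, 1), 1)

  # brute-force pair counting with ties on random data, plus pROC oracle
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    scores <- sample(seq(-1, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    y <- sample(rep(pib_levels(), c(120, 80)))
    pos <- scores[y == "PiB_positive"]; neg <- scores[y == "PiB_negative"]
    brute <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
      (length(pos) * length(neg))
    expect_equal(roc_auc(scores, y)$auc, brute, tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      oracle <- as.numeric(pROC::auc(pROC::roc(
        response = y, predictor = scores, levels = pib_levels(),
        direction = "<", quiet = TRUE)))
      expect_equal(roc_auc(scores, y)$auc, oracle, tolerance = 1e-12)
    }
  }
  expect_error(roc_auc(1:3, rep("PiB_positive", 3)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(12)
  y <- sample(rep(pib_levels(), c(500, 500)))
  expect_lt(abs(roc_auc(rnorm(1000), y)$auc - 0.5), 0.05)
})

test_that("learning curve endpoints coincide with batch training", {
  coh <- fix_cohort(seed = 42)
  X <- build_feature_matrix(coh, fix_geometry()$bases, "combined", N_c = 15)
  y <- coh$labels
  tr <- which(make_folds(y, 5, 7) != 1); te <- which(make_folds(y, 5, 7) == 1)

  batch_acc <- mean(predict_subject(train_batch(X[tr, ], y[tr]),
                                    X[te, ])$label == y[te])
  # single order, one batch containing everything: one point, equal to batch
  lc1 <- learning_curve(X[tr, ], y[tr], X[te, ], y[te],
                        n_orders = 1, batch_size = length(tr), seed = 5)
  expect_identical(lc1$sizes, length(tr))
  expect_equal(unname(lc1$mean_accuracy), batch_acc)

  # several random orders in batches of 10: final point exactly batch accuracy
  lc <- learning_curve(X[tr, ], y[tr], X[te, ], y[te],
                       n_orders = 4, batch_size = 10, seed = 6)
  expect_true(all(diff(lc$sizes) > 0))
  expect_identical(utils::tail(lc$sizes, 1), length(tr))
  expect_true(all(lc$accuracy[, ncol(lc$accuracy)] == batch_acc))
})

test_that("permutation p-values obey the add-one percentile rule", {
  coh <- fix_cohort(seed = 43)
  X <- build_feature_matrix(coh, fix_geometry()$bases, "combined", N_c = 15)
  pt <- permutation_test(X, coh$labels, n_perm = 99, seed = 4, k = 10)
  expect_equal(pt$p_value,
               (1 + sum(pt$null >= pt$observed)) / (1 + pt$n_perm))
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  # planted effect at 2x smooth noise SD: observed beats all 99 permutations
  expect_equal(pt$p_value, 0.01)
  # the fast path's observed statistic equals a plain CV run on the same folds
  cv <- run_cv(X, coh$labels, k = 10, seed = 4)
  expect_equal(pt$observed, cv$accuracy)
})

test_that("a hopeless statistic gets the maximal p-value", {
  # leave-one-out anti-learning pathology: both classes share mean zero, so
  # removing a subject pushes its own class mean away from it and every
  # held-out prediction is wrong; observed accuracy 0 sits below (or ties)
  # every null accuracy, and the add-one rule returns exactly 1
  X <- matrix(c(-3, -1, 1, 3, -4, -2, 2, 4), ncol = 1)
  y <- rep(c("PiB_positive", "PiB_negative"), each = 4)
  pt <- permutation_test(X, y, n_perm = 49, seed = 5, k = 8)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1.0)
})
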