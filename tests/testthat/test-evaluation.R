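test_that("fold plans stratify, partition and reproduce", {
  y <- rep(c(1, 0), times = c(51, 49))
  plan <- make_fold_plan(y, k = 10, repeats = 5, seed = 1)
  expect_equal(dim(plan$assignments), c(100L, 5L))

  seen <- character(0)
  for (r in 1:5) {
    folds <- plan$assignments[, r]
    expect_setequal(unique(folds), 1:10)
    # union of test folds = all subjects, pairwise disjoint (a partition)
    expect_equal(sort(unlist(lapply(1:10, function(f) which(folds == f)))),
                 1:100)
    for (f in 1:10) {
      # stratification counting oracle: case count within +-1 of n_case/k
      n_case_f <- sum(y[folds == f] == 1)
      expect_lte(abs(n_case_f - 5.1), 1)
      seen <- c(seen, paste(which(folds == f), collapse = ","))
    }
  }
  expect_equal(length(unique(seen)), 50L)  # 50 distinct test sets

  expect_identical(make_fold_plan(y, 10, 5, seed = 1)$assignments,
                   plan$assignments)
  expect_error(make_fold_plan(rep(c(0, 1), c(95, 5)), k = 10), "fewer than")
})

test_that("confusion counts follow the definitions with case positive", {
  eq <- confusion_counts(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unclass(eq)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))

  allpos <- confusion_counts(c(1, 1, 0, 0, 0), rep(1, 5))
  expect_equal(allpos$TN, 0L)
  expect_equal(allpos$FP, 3L)

  # hand enumeration
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "lengths")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas match direct arithmetic", {
  counts <- structure(list(TP = 96L, TN = 95L, FP = 5L, FN = 4L),
                      class = "confusion_counts")
  m <- compute_metrics(counts)
  expect_equal(m$accuracy, (96 + 95) / 200)
  expect_equal(m$sensitivity, 96 / 100)
  expect_equal(m$specificity, 95 / 100)
  expect_equal(m$precision, 96 / 101)
  expect_equal(m$f1, 2 * (96 / 101) * 0.96 / ((96 / 101) + 0.96))

  perfect <- compute_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))

  # zero-denominator guard: no positive predictions
  guarded <- compute_metrics(confusion_counts(c(1, 0, 0), c(0, 0, 0)))
  expect_equal(guarded$precision, 0)
  expect_true("precision" %in% guarded$undefined)

  expect_error(compute_metrics(structure(list(TP = 0L, TN = 0L, FP = 0L,
                                              FN = 0L),
                                         class = "confusion_counts")),
               "empty")
})

test_that("ROC/AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  # random scores at n = 1000 per class: AUC ~ 0.5 and identical to the
  # rank-based U statistic
  set.seed(8)
  y <- rep(c(0, 1), each = 1000)
  s <- rnorm(2000)
  res <- roc_auc(y, s)
  se <- sqrt((1000 + 1000 + 1) / (12 * 1000 * 1000))
  expect_close(res$auc, 0.5, tol = 3 * se)
  r <- rank(s)
  u <- sum(r[y == 1]) - 1000 * 1001 / 2
  expect_equal(res$auc, u / (1000 * 1000), tolerance = 1e-12)

  # curve endpoints and monotonicity
  expect_equal(res$curve$fpr[1], 0)
  expect_equal(res$curve$tpr[nrow(res$curve)], 1)
  expect_true(all(diff(res$curve$fpr) >= 0) && all(diff(res$curve$tpr) >= 0))

  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "positive and one negative")
})

fast_experiment_config <- function(seed = 1, models = available_models()) {
  list(
    models = list(enabled = models,
                  hyperparams = list(random_forest = list(n_trees = 30L),
                                     gradient_boosting = list(n_rounds = 30L))),
    gwo = list(pop_size = 4L, n_iter = 3L,
               fitness = list(classifier = "random_forest", cv_folds = 3L,
                              hyperparams = list(n_trees = 15L))),
    evaluation = list(k = 5L, repeats = 1L),
    seed = seed)
}

test_that("run_experiment reports every model in both conditions", {
  cohort <- make_test_cohort(n_control = 40, n_case = 40, seed = 9,
                             n_features = 5, delta = 2)
  report <- run_experiment(cohort, fast_experiment_config())
  expect_s3_class(report, "ws_report")
  expect_equal(nrow(report$metrics), 10L)  # 5 models x 2 conditions
  expect_setequal(unique(report$metrics$model), available_models())
  expect_setequal(unique(report$metrics$condition),
                  c("all_features", "gwo_selected"))
  for (col in c("accuracy", "recall", "specificity", "precision", "f1",
                "auc", "auc_pooled"))
    expect_true(all(is.finite(report$metrics[[col]])), info = col)
  expect_equal(length(report$roc), 10L)
  expect_true(all(c("random_forest", "gradient_boosting") %in%
                    report$importances$model))
  imp_sums <- tapply(report$importances$importance,
                     paste(report$importances$model,
                           report$importances$condition),
                     sum)
  expect_true(all(abs(imp_sums - 1) < 1e-9))

  # strongly separable cohort: tree models well above chance
  tree_acc <- report$metrics$accuracy[
    report$metrics$model %in% c("random_forest", "gradient_boosting")]
  expect_true(all(tree_acc > 0.9))
})

test_that("run_experiment is deterministic under a fixed seed", {
  cohort <- make_test_cohort(n_control = 30, n_case = 30, seed = 10,
                             n_features = 4, delta = 1)
  cfg <- fast_experiment_config(seed = 5,
                                models = c("random_forest",
                                           "logistic_regression"))
  r1 <- run_experiment(cohort, cfg)
  r2 <- run_experiment(cohort, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$selection$best_mask, r2$selection$best_mask)
})
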