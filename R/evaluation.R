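#' Repeated stratified fold assignment
#'
#' Within each repeat and each class, subjects are shuffled and dealt to the
#' `k` folds round-robin, so per-fold class counts differ by at most one
#' from perfect stratification and the folds partition all subjects.
#'
#' @param labels binary 0/1 (or two-level) label vector.
#' @param k folds per repeat (default 10).
#' @param repeats independent partitions (default 5).
#' @param seed integer seed.
#' @return A list of class `fold_plan`: `assignments` (n x repeats integer
#'   matrix of fold ids), `k`, `repeats`, `seed`.
#' @export
make_fold_plan <- function(labels, k = 10L, repeats = 5L, seed = 0L) {
  y <- as.integer(factor(labels))
  cnt <- table(y)
  if (any(cnt < k))
    stop(sprintf("smallest class has %d members, fewer than k = %d",
                 min(cnt), k), call. = FALSE)
  n <- length(y)
  with_seed(seed, {
    assignments <- matrix(NA_integer_, nrow = n, ncol = repeats)
    for (r in seq_len(repeats)) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        assignments[idx, r] <- rep(seq_len(k), length.out = length(idx))
      }
    }
    structure(list(assignments = assignments, k = as.integer(k),
                   repeats = as.integer(repeats), seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' Confusion-matrix counts
#'
#' Case (label 1) is the positive class throughout.
#'
#' @param y_true,y_pred equal-length binary 0/1 vectors.
#' @return A list of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` lengths differ", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Standard definitions: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`,
#' F1 `2PR/(P+R)`. A zero denominator yields 0 and the metric's name is
#' recorded in the `undefined` attribute rather than returning `NaN`.
#'
#' @param counts a `confusion_counts`.
#' @return A list of class `metric_set` with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc` (`NA` here; see [roc_auc()]).
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("empty confusion counts", call. = FALSE)
    undefined <- character(0)
    safe <- function(num, den, name) {
      if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
    }
    acc <- (TP + TN) / total
    sens <- safe(TP, TP + FN, "sensitivity")
    spec <- safe(TN, TN + FP, "specificity")
    prec <- safe(TP, TP + FP, "precision")
    f1 <- safe(2 * prec * sens, prec + sens, "f1")
    structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                   precision = prec, f1 = f1, auc = NA_real_,
                   undefined = undefined),
              class = "metric_set")
  })
}

#' ROC curve and AUC
#'
#' The curve is built by sweeping thresholds over the distinct score values
#' (ties grouped, so tied scores contribute diagonal segments); the AUC is
#' the trapezoidal area, which with this tie handling equals the normalized
#' Mann-Whitney U statistic `U / (n_pos * n_neg)`.
#'
#' @param y_true binary 0/1 labels with at least one of each class.
#' @param scores numeric scores, higher = more case-like.
#' @return A list with `curve` (`data.frame(threshold, fpr, tpr)`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("`y_true` and `scores` lengths differ", call. = FALSE)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)  # tie groups collapsed
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  curve <- data.frame(threshold = c(Inf, s[last_of_group]),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' @noRd
experiment_config <- function(config = list()) {
  defaults <- list(
    elimination_threshold = 0.5,
    models = list(enabled = available_models(), hyperparams = list()),
    gwo = list(pop_size = 10L, n_iter = 20L, transfer = "sigmoid_stochastic",
               min_features = 1L, penalty_weight = 0,
               fitness = list(classifier = "random_forest", cv_folds = 5L,
                              hyperparams = list()),
               scope = "global"),
    evaluation = list(k = 10L, repeats = 5L),
    seed = 0L
  )
  cfg <- modifyList(defaults, config)
  if (!cfg$gwo$scope %in% c("global", "per_fold"))
    stop("gwo scope must be 'global' or 'per_fold'", call. = FALSE)
  bad <- setdiff(cfg$models$enabled, available_models())
  if (length(bad)) stop("unknown model in models.enabled: ", bad[1],
                        call. = FALSE)
  cfg
}

# Preprocess a train/test split without leakage: imputer fitted on the
# training rows only, then sex encoding; returns designs plus a fitted
# scaler for the scale-sensitive models.
#' @noRd
prepare_split <- function(train_tab, test_tab) {
  imp <- fit_imputer(train_tab)
  train_tab <- encode_sex(apply_imputer(imp, train_tab))
  test_tab <- encode_sex(apply_imputer(imp, test_tab))
  train <- cohort_design(train_tab)
  test <- cohort_design(test_tab)
  scaler <- fit_scaler(train$X)
  list(train = train, test = test, scaler = scaler, imputer = imp)
}

#' Run the full before/after-selection benchmark
#'
#' For every repeat and fold of a stratified plan: fit the imputer and
#' scaler on the training rows, train every enabled model on (a) all
#' features and (b) the GWO-selected subset, and score the held-out fold.
#' Per-model metrics are unweighted means over all `k * repeats` folds
#' (per-fold class counts differ by at most one, so weighting is
#' immaterial). Feature elimination uses overall missingness, and — in the
#' default `"global"` scope, mirroring a select-once-then-cross-validate
#' workflow — GWO runs once on the fully preprocessed data; `"per_fold"`
#' scope instead nests selection inside every training fold for
#' leakage-free estimation.
#'
#' @param cohort a `cohort_table` with both groups.
#' @param config nested list overriding defaults: `elimination_threshold`,
#'   `models` (`enabled`, `hyperparams$<id>`, per-model lists), `gwo`
#'   (`pop_size`, `n_iter`, `transfer`, `penalty_weight`, `scope`,
#'   `fitness = list(classifier, cv_folds, hyperparams)`), `evaluation`
#'   (`k`, `repeats`), `seed`.
#' @return A list of class `ws_report`: `metrics` data.frame (`model`,
#'   `condition`, `accuracy`, `recall`, `specificity`, `precision`, `f1`,
#'   `auc` = mean per-fold AUC, `auc_pooled` from the last repeat's pooled
#'   out-of-fold scores), `roc` (per model x condition curves), `selection`
#'   (the `selection_result`, `NULL` in per-fold scope), `importances`,
#'   `fold_plan`, `dropped_features`, `config`.
#' @export
run_experiment <- function(cohort, config = list()) {
  cfg <- experiment_config(config)
  seed <- cfg$seed

  elim <- eliminate_features(cohort, cfg$elimination_threshold)
  cohort <- elim$table
  y_all <- as.integer(cohort$group == "case")
  if (length(unique(y_all)) < 2L)
    stop("cohort must contain both groups", call. = FALSE)

  gwo_par <- gwo_params(pop_size = cfg$gwo$pop_size, n_iter = cfg$gwo$n_iter,
                        seed = derive_seed(seed, "gwo"),
                        transfer = cfg$gwo$transfer,
                        min_features = cfg$gwo$min_features,
                        penalty_weight = cfg$gwo$penalty_weight)
  fit_spec <- fitness_spec(cfg$gwo$fitness$classifier, cfg$gwo$fitness$cv_folds,
                           seed = derive_seed(seed, "gwo_fitness"),
                           hyperparams = cfg$gwo$fitness$hyperparams)

  selection <- NULL
  global_mask <- NULL
  if (cfg$gwo$scope == "global") {
    full_imp <- fit_imputer(cohort)
    full_tab <- encode_sex(apply_imputer(full_imp, cohort))
    selection <- run_gwo(full_tab, gwo_par, fit_spec)
    global_mask <- selection$best_mask
  }

  plan <- make_fold_plan(y_all, k = cfg$evaluation$k,
                         repeats = cfg$evaluation$repeats,
                         seed = derive_seed(seed, "folds"))

  models <- cfg$models$enabled
  conditions <- c("all_features", "gwo_selected")
  key <- function(m, cond) paste(m, cond, sep = ".")
  fold_metrics <- list()
  pooled <- list()  # last repeat's out-of-fold scores, per model x condition

  for (r in seq_len(plan$repeats)) {
    folds <- plan$assignments[, r]
    for (f in seq_len(plan$k)) {
      test_idx <- folds == f
      split <- prepare_split(cohort[!test_idx, , drop = FALSE],
                             cohort[test_idx, , drop = FALSE])
      mask <- if (cfg$gwo$scope == "global") global_mask else
        run_gwo(split$train,
                gwo_params(pop_size = gwo_par$pop_size, n_iter = gwo_par$n_iter,
                           seed = derive_seed(seed, sprintf("gwo_r%d_f%d", r, f)),
                           transfer = gwo_par$transfer,
                           min_features = gwo_par$min_features,
                           penalty_weight = gwo_par$penalty_weight),
                fit_spec)$best_mask

      for (m in models) {
        needs_scale <- scale_sensitive(m)
        Xtr0 <- if (needs_scale) apply_scaler(split$scaler, split$train$X) else
          split$train$X
        Xte0 <- if (needs_scale) apply_scaler(split$scaler, split$test$X) else
          split$test$X
        mspec <- model_spec(m, cfg$models$hyperparams[[m]] %||% list(),
                            seed = derive_seed(seed, paste0("model_", m)))
        for (cond in conditions) {
          keep <- if (cond == "all_features") rep(TRUE, ncol(Xtr0)) else
            as.logical(mask)
          fitted <- train_model(mspec, Xtr0[, keep, drop = FALSE],
                                split$train$y)
          sc <- predict_scores(fitted, Xte0[, keep, drop = FALSE])
          pred <- predict_labels(fitted, sc)
          met <- compute_metrics(confusion_counts(split$test$y, pred))
          met$auc <- roc_auc(split$test$y, sc)$auc
          kk <- key(m, cond)
          fold_metrics[[kk]] <- c(fold_metrics[[kk]], list(met))
          if (r == plan$repeats) {
            pooled[[kk]]$y <- c(pooled[[kk]]$y, split$test$y)
            pooled[[kk]]$scores <- c(pooled[[kk]]$scores, sc)
          }
        }
      }
    }
  }

  rows <- list()
  roc_curves <- list()
  for (m in models) for (cond in conditions) {
    kk <- key(m, cond)
    mets <- fold_metrics[[kk]]
    avg <- function(field) mean(vapply(mets, `[[`, numeric(1), field))
    pr <- roc_auc(pooled[[kk]]$y, pooled[[kk]]$scores)
    roc_curves[[kk]] <- pr$curve
    rows[[kk]] <- data.frame(
      model = m, condition = cond,
      accuracy = avg("accuracy"), recall = avg("sensitivity"),
      specificity = avg("specificity"), precision = avg("precision"),
      f1 = avg("f1"), auc = avg("auc"), auc_pooled = pr$auc,
      stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # Tree-model importances on the fully preprocessed data, both conditions
  importances <- NULL
  full_tab <- encode_sex(apply_imputer(fit_imputer(cohort), cohort))
  full <- cohort_design(full_tab)
  imp_mask <- global_mask %||% rep(1L, ncol(full$X))
  for (m in intersect(models, c("random_forest", "gradient_boosting"))) {
    mspec <- model_spec(m, cfg$models$hyperparams[[m]] %||% list(),
                        seed = derive_seed(seed, paste0("model_", m)))
    for (cond in conditions) {
      keep <- if (cond == "all_features") rep(TRUE, ncol(full$X)) else
        as.logical(imp_mask)
      fitted <- train_model(mspec, full$X[, keep, drop = FALSE], full$y)
      imp <- feature_importances(fitted)
      importances <- rbind(importances, data.frame(
        model = m, condition = cond, feature = names(imp),
        importance = as.numeric(imp), stringsAsFactors = FALSE))
    }
  }

  structure(list(metrics = metrics, roc = roc_curves, selection = selection,
                 importances = importances, fold_plan = plan,
                 dropped_features = elim$dropped, config = cfg),
            class = "ws_report")
}

#' @export
print.ws_report <- function(x, ...) {
  cat("Cross-validated performance (mean over",
      x$fold_plan$k * x$fold_plan$repeats, "folds):\n")
  print(x$metrics, digits = 4, row.names = FALSE)
  if (!is.null(x$selection))
    cat(sprintf("\nGWO selected %d/%d features.\n", x$selection$n_selected,
                length(x$selection$best_mask)))
  invisible(x)
}
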