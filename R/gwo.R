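#' Design matrix of a preprocessed cohort
#'
#' Assembles the numeric matrix handed to classifiers and the feature
#' selector: one column per lab analyte, plus `age` and the encoded `sex`
#' bit. Labels are 1 for cases (the positive class) and 0 for controls.
#'
#' @param table a complete, sex-encoded `cohort_table`.
#' @return A list with `X` (numeric matrix with column names) and `y`
#'   (integer 0/1 labels).
#' @export
cohort_design <- function(table) {
  if (!is.numeric(table$sex))
    stop("encode sex before building the design matrix", call. = FALSE)
  feats <- c(lab_features(table), "age", "sex")
  X <- as.matrix(as.data.frame(table, check.names = FALSE)[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("design matrix has missing values; impute first",
                     call. = FALSE)
  list(X = X, y = as.integer(table$group == "case"))
}

#' Grey Wolf Optimizer parameters
#'
#' Defaults follow the canonical configuration for wrapper feature selection
#' on clinical tabular data: a pack of 10 wolves, 20 iterations, and an
#' exploration coefficient `a` decaying linearly from 2 to 0. Continuous
#' positions are mapped to feature bits by a transfer function:
#' `"sigmoid_stochastic"` (default) includes feature `j` with probability
#' `1 / (1 + exp(-10 (pos_j - 0.5)))`; `"threshold_half"` deterministically
#' includes it iff `pos_j > 0.5`. Masks with fewer than `min_features` bits
#' are repaired by switching on the largest-position components.
#' `penalty_weight` subtracts `penalty_weight * popcount/d` from the fitness
#' (default 0: fitness is pure cross-validated accuracy; parsimony enters
#' only as a tie-break).
#'
#' @param pop_size number of wolves (>= 2).
#' @param n_iter number of iterations (>= 1).
#' @param seed integer seed for the optimizer's randomness.
#' @param a_start,a_end endpoints of the linear decay of `a`.
#' @param transfer `"sigmoid_stochastic"` or `"threshold_half"`.
#' @param min_features minimum selected features (>= 1).
#' @param penalty_weight subset-size penalty weight (>= 0).
#' @return A list of class `gwo_params`.
#' @export
gwo_params <- function(pop_size = 10L, n_iter = 20L, seed = 0L,
                       a_start = 2, a_end = 0,
                       transfer = c("sigmoid_stochastic", "threshold_half"),
                       min_features = 1L, penalty_weight = 0) {
  transfer <- match.arg(transfer)
  if (pop_size < 2) stop("`pop_size` must be >= 2", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  if (min_features < 1) stop("`min_features` must be >= 1", call. = FALSE)
  if (penalty_weight < 0) stop("`penalty_weight` must be >= 0", call. = FALSE)
  structure(list(pop_size = as.integer(pop_size), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), a_start = a_start, a_end = a_end,
                 transfer = transfer, min_features = as.integer(min_features),
                 penalty_weight = penalty_weight),
            class = "gwo_params")
}

#' Fitness specification for wrapper selection
#'
#' The fitness of a candidate mask is the mean stratified `cv_folds`-fold
#' cross-validated accuracy of the wrapper classifier trained on the masked
#' columns (minus the optional subset-size penalty). Deterministic given
#' `seed`.
#'
#' @param classifier_id wrapper classifier (default `"random_forest"`).
#' @param cv_folds number of stratified folds (>= 2).
#' @param seed integer seed for fold assignment and the classifier.
#' @param hyperparams hyperparameter overrides for the wrapper classifier.
#' @return A list of class `fitness_spec`.
#' @export
fitness_spec <- function(classifier_id = "random_forest", cv_folds = 5L,
                         seed = 0L, hyperparams = list()) {
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  if (!classifier_id %in% available_models())
    stop("unknown classifier_id: ", classifier_id, call. = FALSE)
  structure(list(classifier_id = classifier_id,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 hyperparams = hyperparams),
            class = "fitness_spec")
}

#' @noRd
scale_sensitive <- function(model_id)
  model_id %in% c("svm_rbf", "knn", "logistic_regression")

#' Cross-validated accuracy of a feature mask
#'
#' @param mask binary vector over the design-matrix columns (>= 1 one).
#' @param train a preprocessed `cohort_table` (complete, sex encoded) or a
#'   list `list(X, y)` as returned by [cohort_design()].
#' @param spec a [fitness_spec()].
#' @param penalty_weight subset-size penalty weight.
#' @return Mean fold accuracy minus `penalty_weight * popcount/d`.
#' @export
evaluate_fitness <- function(mask, train, spec = fitness_spec(),
                             penalty_weight = 0) {
  if (sum(mask) < 1) stop("mask selects no features; repair first",
                          call. = FALSE)
  design <- if (inherits(train, "cohort_table")) cohort_design(train) else train
  X <- design$X[, as.logical(mask), drop = FALSE]
  y <- design$y
  plan <- make_fold_plan(y, k = spec$cv_folds, repeats = 1L,
                         seed = derive_seed(spec$seed, "fitness_folds"))
  folds <- plan$assignments[, 1]
  mspec <- model_spec(spec$classifier_id, spec$hyperparams, seed = spec$seed)
  correct <- 0L
  for (f in seq_len(spec$cv_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (scale_sensitive(spec$classifier_id)) {
      sc <- fit_scaler(Xtr)
      Xtr <- apply_scaler(sc, Xtr)
      Xte <- apply_scaler(sc, Xte)
    }
    m <- train_model(mspec, Xtr, y[!test])
    pred <- predict_labels(m, predict_scores(m, Xte))
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y) - penalty_weight * sum(mask) / length(mask)
}

#' Map a continuous wolf position to a feature mask
#'
#' @param position numeric vector in `[0, 1]^d`.
#' @param params a [gwo_params()]; `params$transfer` selects the transfer
#'   function and `params$min_features` the repair floor.
#' @return Integer 0/1 mask of the same length. Uses the current RNG state
#'   when the transfer is stochastic.
#' @export
binarize <- function(position, params = gwo_params()) {
  mask <- if (params$transfer == "threshold_half") {
    as.integer(position > 0.5)
  } else {
    p_incl <- 1 / (1 + exp(-10 * (position - 0.5)))
    as.integer(p_incl > runif(length(position)))
  }
  if (sum(mask) < params$min_features) {
    # repair: keep the ranking signal by switching on the largest positions
    top <- order(position, decreasing = TRUE)[seq_len(params$min_features)]
    mask[top] <- 1L
  }
  mask
}

#' Initialize a wolf pack
#'
#' Positions are i.i.d. uniform on `[0, 1]^d`; masks come from [binarize()].
#' Fitness values start unset; leaders are assigned after the first
#' evaluation. Uses the current RNG state.
#'
#' @param d number of features (>= `params$min_features`).
#' @param params a [gwo_params()].
#' @return A list of class `wolf_pack` with `positions` and `masks`
#'   (`pop_size x d` matrices), `fitness`, `leaders`, `iteration`.
#' @export
initialize_pack <- function(d, params = gwo_params()) {
  if (d < 1) stop("`d` must be >= 1", call. = FALSE)
  if (d < params$min_features)
    stop("`d` is smaller than `min_features`", call. = FALSE)
  positions <- matrix(runif(params$pop_size * d), nrow = params$pop_size)
  masks <- t(apply(positions, 1, binarize, params = params))
  if (d == 1L) masks <- matrix(as.integer(masks), ncol = 1L)
  structure(list(positions = positions, masks = masks,
                 fitness = rep(NA_real_, params$pop_size),
                 leaders = NULL, iteration = 0L),
            class = "wolf_pack")
}

# Rank wolves: higher fitness first, then fewer selected features, then
# earlier index. Returns the ordering permutation.
#' @noRd
rank_wolves <- function(fitness, masks) {
  order(-fitness, rowSums(masks), seq_along(fitness))
}

#' One position update of the pack
#'
#' Canonical three-leader update: for each wolf and each leader L in
#' {alpha, beta, delta}, draw `r1, r2` uniform per component, set
#' `A = 2 a r1 - a`, `C = 2 r2`, `D = |C X_L - X|`, `X_L' = X_L - A D`; the
#' new position is the mean of the three attraction points, clamped to
#' `[0, 1]`. Uses the current RNG state.
#'
#' @param pack a `wolf_pack` with `leaders` assigned.
#' @param a exploration coefficient in `[0, 2]`.
#' @return The pack with updated `positions` (masks/fitness untouched).
#' @export
update_positions <- function(pack, a) {
  if (is.null(pack$leaders)) stop("pack leaders not assigned", call. = FALSE)
  d <- ncol(pack$positions)
  leaders <- pack$positions[pack$leaders, , drop = FALSE]
  for (i in seq_len(nrow(pack$positions))) {
    x <- pack$positions[i, ]
    attract <- matrix(0, nrow = 3, ncol = d)
    for (L in 1:3) {
      r1 <- runif(d); r2 <- runif(d)
      A <- 2 * a * r1 - a
      C <- 2 * r2
      D <- abs(C * leaders[L, ] - x)
      attract[L, ] <- leaders[L, ] - A * D
    }
    pack$positions[i, ] <- pmin(pmax(colMeans(attract), 0), 1)
  }
  pack
}

#' Run binary Grey Wolf wrapper feature selection
#'
#' Executes `params$n_iter` iterations with the exploration coefficient `a`
#' decaying linearly from `a_start` to `a_end`, re-binarizing and
#' re-evaluating every wolf each iteration and updating the alpha/beta/delta
#' leaders greedily. The best-ever mask is tracked with a parsimony
#' tie-break: equal fitness with strictly fewer features replaces the
#' incumbent; otherwise the earlier-encountered mask is kept. Fitness
#' evaluations are memoized (the fitness is deterministic given
#' `spec$seed`, so repeated masks are looked up, not re-evaluated).
#'
#' @param train preprocessed `cohort_table` or `list(X, y)` design.
#' @param params a [gwo_params()].
#' @param spec a [fitness_spec()].
#' @return A list of class `selection_result`: `best_mask`, `best_fitness`,
#'   `n_selected`, `trace` (best-so-far fitness after initialization and
#'   after each iteration; non-decreasing), `feature_names`,
#'   `selected_features`, `n_evaluations`.
#' @export
run_gwo <- function(train, params = gwo_params(), spec = fitness_spec()) {
  design <- if (inherits(train, "cohort_table")) cohort_design(train) else train
  d <- ncol(design$X)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluate_fitness(mask, design, spec, params$penalty_weight)
    n_eval <<- n_eval + 1L
    cache[[key]] <- val
    val
  }

  with_seed(params$seed, {
    pack <- initialize_pack(d, params)
    pack$fitness <- apply(pack$masks, 1, fitness_of)

    best_mask <- NULL
    best_fitness <- -Inf
    consider <- function(mask, fit) {
      if (fit > best_fitness ||
          (fit == best_fitness && sum(mask) < sum(best_mask))) {
        best_mask <<- mask
        best_fitness <<- fit
      }
    }
    for (i in seq_len(params$pop_size))
      consider(pack$masks[i, ], pack$fitness[i])

    pack$leaders <- rank_wolves(pack$fitness, pack$masks)[1:3]
    trace <- best_fitness

    for (iter in seq_len(params$n_iter)) {
      a <- if (params$n_iter == 1L) params$a_end else
        params$a_start - (params$a_start - params$a_end) * (iter - 1) /
          (params$n_iter - 1)
      pack <- update_positions(pack, a)
      pack$masks <- t(apply(pack$positions, 1, binarize, params = params))
      if (d == 1L) pack$masks <- matrix(as.integer(pack$masks), ncol = 1L)
      pack$fitness <- apply(pack$masks, 1, fitness_of)
      for (i in seq_len(params$pop_size))
        consider(pack$masks[i, ], pack$fitness[i])
      pack$leaders <- rank_wolves(pack$fitness, pack$masks)[1:3]
      pack$iteration <- iter
      trace <- c(trace, best_fitness)
    }

    feature_names <- colnames(design$X)
    structure(list(best_mask = best_mask, best_fitness = best_fitness,
                   n_selected = sum(best_mask), trace = trace,
                   feature_names = feature_names,
                   selected_features = feature_names[as.logical(best_mask)],
                   n_evaluations = n_eval),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("GWO selection: %d/%d features, best fitness %.4f (%d unique evaluations)\n",
              x$n_selected, length(x$best_mask), x$best_fitness,
              x$n_evaluations))
  cat("selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
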