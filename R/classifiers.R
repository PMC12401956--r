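#' Classifier specification
#'
#' The five reference models and their default hyperparameters:
#' \describe{
#'   \item{`random_forest`}{100 Gini CART trees, `mtry = floor(sqrt(d))`
#'     features per split, grown to purity (`max_depth = 0` = unlimited,
#'     `min_split = 2`), bootstrap resampling.}
#'   \item{`gradient_boosting`}{100 boosting rounds of depth-6 trees,
#'     learning rate 0.3, L2 penalty `lambda = 1`, `gamma = 0`,
#'     `min_child_weight = 1`, logistic loss, base score 0.5.}
#'   \item{`logistic_regression`}{ridge-penalized logistic regression with
#'     inverse regularization strength `C = 1` (intercept unpenalized),
#'     fitted by Newton iterations.}
#'   \item{`svm_rbf`}{soft-margin SVM, RBF kernel, `cost = 1`,
#'     `gamma = "scale"` (i.e. `1 / (d * var(X))`), solved as the dual QP.}
#'   \item{`knn`}{k-nearest neighbours, `k = 5`, Euclidean distance; `k` is
#'     clipped to `n - 1` with a warning on tiny training sets.}
#' }
#' Scale-sensitive models (`svm_rbf`, `knn`, `logistic_regression`) expect
#' standardized inputs; see [fit_scaler()].
#'
#' @param model_id one of `"random_forest"`, `"logistic_regression"`,
#'   `"svm_rbf"`, `"knn"`, `"gradient_boosting"`.
#' @param hyperparams named list overriding the defaults above.
#' @param seed integer seed (used by the stochastic tree learners).
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec("random_forest", list(n_trees = 50), seed = 1)
model_spec <- function(model_id, hyperparams = list(), seed = 0L) {
  defaults <- switch(model_id,
    random_forest = list(n_trees = 100L, mtry = NA_integer_, min_split = 2L,
                         max_depth = 0L),
    gradient_boosting = list(n_rounds = 100L, eta = 0.3, max_depth = 6L,
                             lambda = 1, gamma = 0, min_child_weight = 1,
                             base_score = 0.5),
    logistic_regression = list(C = 1.0, max_iter = 100L, tol = 1e-9),
    svm_rbf = list(cost = 1.0, gamma = "scale"),
    knn = list(k = 5L),
    stop("unknown model_id: ", model_id, call. = FALSE)
  )
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown hyperparameter '%s' for model '%s'", unknown[1],
                 model_id), call. = FALSE)
  structure(list(model_id = model_id,
                 hyperparams = modifyList(defaults, hyperparams),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Model identifiers of the classifier zoo
#' @return Character vector of the five supported `model_id`s.
#' @export
available_models <- function() {
  c("random_forest", "logistic_regression", "svm_rbf", "knn",
    "gradient_boosting")
}

#' Train a classifier
#'
#' @param spec a [model_spec()].
#' @param X complete numeric feature matrix (rows = subjects) with column
#'   names; standardized for the scale-sensitive models.
#' @param y binary labels, 1 = case (positive class), 0 = control.
#' @return A fitted model of class `ws_model`; pass to [predict_scores()].
#' @export
train_model <- function(spec, X, y) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec",
                                          call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty feature matrix",
                                           call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("`y` must be binary 0/1", call. = FALSE)
  storage.mode(X) <- "double"
  hp <- spec$hyperparams
  fit <- switch(spec$model_id,
    random_forest = {
      mtry <- hp$mtry
      if (is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
      .rf_fit_cpp(X, y, as.integer(hp$n_trees), as.integer(mtry),
                  as.integer(hp$min_split), as.integer(hp$max_depth),
                  spec$seed)
    },
    gradient_boosting = .gbt_fit_cpp(X, y, as.integer(hp$n_rounds), hp$eta,
                                     as.integer(hp$max_depth), hp$lambda,
                                     hp$gamma, hp$min_child_weight,
                                     hp$base_score),
    logistic_regression = fit_ridge_logistic(X, y, C = hp$C,
                                             max_iter = hp$max_iter,
                                             tol = hp$tol),
    svm_rbf = fit_svm_rbf(X, y, cost = hp$cost, gamma = hp$gamma),
    knn = {
      k <- as.integer(hp$k)
      if (k >= nrow(X)) {
        k <- nrow(X) - 1L
        warning(sprintf("k clipped to n - 1 = %d", k), call. = FALSE)
      }
      list(X = X, y = y, k = max(1L, k))
    }
  )
  structure(list(spec = spec, fit = fit, feature_names = colnames(X),
                 trained = TRUE),
            class = c(paste0("ws_model_", spec$model_id), "ws_model"))
}

#' Score subjects with a fitted classifier
#'
#' Scores are oriented so that higher means more case-like: class-case
#' probabilities for the probabilistic models (threshold 0.5 for hard
#' labels) and the signed decision value for the SVM (threshold 0).
#'
#' @param model a fitted `ws_model`.
#' @param X feature matrix with the model's feature columns.
#' @return Numeric score vector, one per row of `X`.
#' @export
predict_scores <- function(model, X) {
  if (!inherits(model, "ws_model") || !isTRUE(model$trained))
    stop("`model` is not a trained ws_model", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names))
      stop("feature count mismatch", call. = FALSE)
    colnames(X) <- model$feature_names
  }
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing))
    stop("missing feature column: ", missing[1], call. = FALSE)
  X <- X[, model$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  fit <- model$fit
  switch(model$spec$model_id,
    random_forest = as.numeric(.forest_predict_cpp(fit$trees, X, TRUE)),
    gradient_boosting = as.numeric(.gbt_predict_cpp(fit, X)),
    logistic_regression = {
      eta <- drop(cbind(1, X) %*% fit$coef)
      1 / (1 + exp(-eta))
    },
    svm_rbf = {
      K <- rbf_kernel(X, fit$sv_X, fit$gamma)
      drop(K %*% fit$sv_coef) + fit$intercept
    },
    knn = {
      nn <- FNN::get.knnx(fit$X, X, k = fit$k)
      rowMeans(matrix(fit$y[nn$nn.index], nrow = nrow(X)))
    }
  )
}

#' Hard labels from scores
#' @param model a fitted `ws_model`.
#' @param scores output of [predict_scores()].
#' @return Integer 0/1 predictions.
#' @export
predict_labels <- function(model, scores) {
  thr <- if (model$spec$model_id == "svm_rbf") 0 else 0.5
  as.integer(scores > thr)
}

#' Normalized feature importances of the tree ensembles
#'
#' Random forest importances are mean Gini impurity decreases; gradient
#' boosting importances are total split gains. Both are normalized to sum
#' to 1; features never used in a split score 0.
#'
#' @param model a fitted `random_forest` or `gradient_boosting` model.
#' @return Named numeric vector (feature -> importance), in feature order.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "ws_model"))
    stop("`model` must be a ws_model", call. = FALSE)
  if (!model$spec$model_id %in% c("random_forest", "gradient_boosting"))
    stop("feature importances unavailable for model '", model$spec$model_id,
         "'", call. = FALSE)
  setNames(as.numeric(model$fit$importance), model$feature_names)
}

# ---- ridge logistic regression -------------------------------------------

# Newton/IRLS minimization of sum log(1 + exp(-y_pm * eta)) + ||w||^2 / (2C),
# intercept unpenalized.
#' @noRd
fit_ridge_logistic <- function(X, y, C = 1, max_iter = 100L, tol = 1e-9) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  lambda <- 1 / C
  R <- diag(c(1e-10, rep(lambda, p - 1L)))  # tiny jitter keeps H invertible
  w <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xi %*% w)
    mu <- 1 / (1 + exp(-eta))
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xi, mu - y)) + R %*% w
    H <- crossprod(Xi * wt, Xi) + R
    step <- solve(H, grad)
    w <- w - step
    if (max(abs(step)) < tol) break
  }
  list(coef = drop(w))
}

# ---- RBF support vector machine ------------------------------------------

#' @noRd
rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Dual soft-margin SVM solved with quadprog:
#   min 1/2 a' (yy' * K) a - 1'a   s.t.  y'a = 0, 0 <= a <= cost
#' @noRd
fit_svm_rbf <- function(X, y, cost = 1, gamma = "scale") {
  n <- nrow(X)
  if (length(unique(y)) < 2L) stop("SVM needs both classes", call. = FALSE)
  if (identical(gamma, "scale")) {
    v <- mean(apply(X, 2, function(col) mean((col - mean(col))^2)))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  ypm <- ifelse(y == 1L, 1, -1)
  K <- rbf_kernel(X, X, gamma)
  D <- K * tcrossprod(ypm)
  dvec <- rep(1, n)
  Amat <- cbind(ypm, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  ridge <- 1e-8
  sol <- NULL
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(D + diag(ridge, n), dvec, Amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("SVM dual QP failed to solve", call. = FALSE)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-7
  if (!any(sv)) sv <- alpha >= max(alpha)  # degenerate: keep the largest
  coef_all <- alpha * ypm
  f0 <- drop(K %*% coef_all)
  margin_sv <- which(alpha > 1e-7 & alpha < cost - 1e-7)
  b <- if (length(margin_sv)) mean(ypm[margin_sv] - f0[margin_sv])
       else mean(ypm[sv] - f0[sv])
  list(sv_X = X[sv, , drop = FALSE], sv_coef = coef_all[sv],
       intercept = b, gamma = gamma)
}
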