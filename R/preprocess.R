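#' Drop features with excess missingness
#'
#' A lab feature is dropped iff its missing fraction over all rows strictly
#' exceeds `threshold`. `group`, `sex` and `age` are never dropped. The
#' default threshold (0.50) removes parameters measured in fewer than half
#' the subjects, which carry little statistical support.
#'
#' @param table a `cohort_table`.
#' @param threshold missing-fraction cutoff in `[0, 1]`.
#' @return A list with `table` (features removed) and `dropped` (character
#'   vector of removed names, possibly empty).
#' @export
eliminate_features <- function(table, threshold = 0.5) {
  assert_scalar_in(threshold, 0, 1, "threshold")
  labs <- lab_features(table)
  frac <- vapply(labs, function(f) mean(is.na(table[[f]])), numeric(1))
  dropped <- labs[frac > threshold]
  if (length(dropped)) {
    table <- table[, setdiff(names(table), dropped), drop = FALSE]
    table <- as_cohort_table(table, lab_features = setdiff(labs, dropped))
  }
  list(table = table, dropped = dropped)
}

#' Fit / apply a median-mode imputer
#'
#' `fit_imputer()` learns, from a training table only, the median of each
#' numeric feature's observed values and the mode of each categorical
#' feature (sex; ties broken by lexicographic order). `apply_imputer()`
#' fills the missing cells of any table with those statistics, leaving
#' observed values untouched — fitting on a training fold and applying to a
#' held-out fold therefore never leaks test-fold information.
#'
#' @param train,table `cohort_table`s; `train` must have at least one
#'   observed value per feature (eliminate fully-missing features first).
#' @param model an `imputer_model` from `fit_imputer()`.
#' @return `fit_imputer` returns an `imputer_model` (fields `medians`,
#'   `modes`, `fitted_on_n`); `apply_imputer` returns a complete table.
#' @export
fit_imputer <- function(train) {
  labs <- lab_features(train)
  medians <- setNames(numeric(0), character(0))
  for (f in c(labs, "age")) {
    obs <- train[[f]][!is.na(train[[f]])]
    if (!length(obs))
      stop("feature entirely missing in training data: ", f, call. = FALSE)
    medians[[f]] <- median(obs)
  }
  sex_obs <- train$sex[!is.na(train$sex)]
  if (!length(sex_obs)) stop("sex entirely missing in training data", call. = FALSE)
  counts <- table(sex_obs)
  mode_sex <- sort(names(counts)[counts == max(counts)])[1]
  structure(list(medians = medians, modes = list(sex = mode_sex),
                 fitted_on_n = nrow(train)),
            class = "imputer_model")
}

#' @rdname fit_imputer
#' @export
apply_imputer <- function(model, table) {
  if (!inherits(model, "imputer_model"))
    stop("`model` must be an imputer_model", call. = FALSE)
  num_feats <- c(lab_features(table), "age")
  unseen <- setdiff(num_feats, names(model$medians))
  if (length(unseen))
    stop("feature not seen by the imputer: ", unseen[1], call. = FALSE)
  for (f in num_feats) {
    miss <- is.na(table[[f]])
    if (any(miss)) table[[f]][miss] <- model$medians[[f]]
  }
  miss <- is.na(table$sex)
  if (any(miss)) table$sex[miss] <- model$modes$sex
  table
}

#' Encode / decode the sex column
#'
#' Fixed convention: `female -> 0`, `male -> 1`. `encode_sex()` requires a
#' complete sex column (impute first).
#'
#' @param table a `cohort_table`.
#' @return The table with `sex` as a numeric 0/1 column (`encode_sex`) or as
#'   labels again (`decode_sex`).
#' @export
encode_sex <- function(table) {
  if (is.numeric(table$sex)) return(table)
  bad <- which(!table$sex %in% c("male", "female"))
  if (length(bad))
    stop(sprintf("row %d: cannot encode sex value '%s'", bad[1],
                 as.character(table$sex[bad[1]])), call. = FALSE)
  table$sex <- as.numeric(table$sex == "male")
  table
}

#' @rdname encode_sex
#' @export
decode_sex <- function(table) {
  if (!is.numeric(table$sex)) return(table)
  table$sex <- ifelse(table$sex == 1, "male", "female")
  table
}

#' Fit / apply a z-score scaler
#'
#' Standardizes numeric features with mean and standard deviation computed
#' on a training table only, as needed by distance-, margin- and
#' penalty-based classifiers (KNN, SVM, logistic regression). A constant
#' training column has its SD replaced by 1, mapping it to all zeros.
#'
#' @param train a `cohort_table` or numeric matrix.
#' @param features which columns to scale; default all numeric features
#'   (labs, age, and sex if already encoded).
#' @param model a `scaler_model`.
#' @param table table or matrix to transform.
#' @return `fit_scaler` returns a `scaler_model` (fields `means`, `sds`);
#'   `apply_scaler` returns the transformed object.
#' @export
fit_scaler <- function(train, features = NULL) {
  if (is.matrix(train)) {
    features <- features %||% colnames(train)
    get <- function(f) train[, f]
  } else {
    features <- features %||% c(lab_features(train), "age",
                                if (is.numeric(train$sex)) "sex")
    get <- function(f) train[[f]]
  }
  means <- sds <- setNames(numeric(length(features)), features)
  for (f in features) {
    x <- get(f)
    if (anyNA(x)) stop("scaler requires complete data; impute first",
                       call. = FALSE)
    means[[f]] <- mean(x)
    s <- stats::sd(x)
    sds[[f]] <- if (!is.finite(s) || s == 0) 1 else s
  }
  structure(list(means = means, sds = sds), class = "scaler_model")
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(model, table) {
  if (!inherits(model, "scaler_model"))
    stop("`model` must be a scaler_model", call. = FALSE)
  feats <- names(model$means)
  if (is.matrix(table)) {
    unseen <- setdiff(colnames(table), feats)
    if (length(unseen))
      stop("feature not seen by the scaler: ", unseen[1], call. = FALSE)
    for (f in colnames(table))
      table[, f] <- (table[, f] - model$means[[f]]) / model$sds[[f]]
    return(table)
  }
  present <- intersect(feats, names(table))
  missing <- setdiff(feats, names(table))
  if (length(missing) && length(present) == 0)
    stop("table has none of the scaler's features", call. = FALSE)
  for (f in present)
    table[[f]] <- (table[[f]] - model$means[[f]]) / model$sds[[f]]
  table
}
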