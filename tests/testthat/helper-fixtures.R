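# Shared fixture builders. All fixtures are built in code at test time.

# A small custom feature-spec table; delta shifts the case means (0 = null
# world with identical group distributions).
make_test_specs <- function(n_features = 6, delta = 0, sd = 1, mean = 50,
                            names = sprintf("feat%02d", seq_len(n_features))) {
  specs <- data.frame(
    name = names, unit = "U",
    control_mean = rep(mean, n_features), control_sd = rep(sd, n_features),
    case_mean = rep(mean + delta, n_features), case_sd = rep(sd, n_features),
    lower_bound = 0, missing_rate = 0,
    stringsAsFactors = FALSE, check.names = FALSE)
  class(specs) <- c("feature_spec_tbl", "data.frame")
  specs
}

make_test_cohort <- function(n_control = 30, n_case = 30, seed = 1,
                             n_features = 6, delta = 0, correlation = 0) {
  generate_cohort(
    cohort_config(n_control = n_control, n_case = n_case, seed = seed,
                  correlation = correlation),
    make_test_specs(n_features, delta = delta))
}

# Write a feature-spec CSV to a temp file and return its path.
write_test_spec_csv <- function(specs, path = tempfile(fileext = ".csv")) {
  write.csv(specs, path, row.names = FALSE, quote = TRUE)
  path
}

# Design matrix with a planted signal: `informative` columns shifted by
# `shift` in the case group, the rest pure noise.
make_planted_design <- function(n_per_class = 60, d = 8, informative = 1:3,
                                shift = 1.2, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- 2 * n_per_class
    y <- rep(c(0L, 1L), each = n_per_class)
    X <- matrix(rnorm(n * d), n, d)
    X[y == 1L, informative] <- X[y == 1L, informative] + shift
    colnames(X) <- sprintf("f%d", seq_len(d))
    list(X = X, y = y)
  })
}

# Small wrapper fitness used wherever tests exercise the optimizer: fewer
# trees than the production default purely for test runtime.
fast_fitness <- function(seed = 1, cv_folds = 5, classifier = "random_forest") {
  fitness_spec(classifier, cv_folds = cv_folds, seed = seed,
               hyperparams = if (classifier == "random_forest")
                 list(n_trees = 25L) else list())
}

expect_close <- function(actual, expected, tol) {
  testthat::expect_true(abs(actual - expected) <= tol,
                        label = sprintf("|%g - %g| <= %g", actual, expected,
                                        tol))
}
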