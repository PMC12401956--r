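test_that("eliminate_features drops on strict threshold exceedance", {
  cohort <- make_test_cohort(n_control = 50, n_case = 50, seed = 1,
                             n_features = 4)
  cohort <- inject_missingness(cohort, c(feat01 = 0.6, feat02 = 1), seed = 2)
  frac1 <- mean(is.na(cohort$feat01))  # ~0.6

  res <- eliminate_features(cohort, threshold = 0.5)
  expect_true("feat01" %in% res$dropped)
  expect_true("feat02" %in% res$dropped)
  expect_false("feat03" %in% res$dropped)
  expect_false("feat01" %in% names(res$table))

  # threshold exactly at the observed fraction: strict inequality keeps it
  res_eq <- eliminate_features(cohort, threshold = frac1)
  expect_false("feat01" %in% res_eq$dropped)

  expect_equal(eliminate_features(cohort, threshold = 1)$dropped, character(0))
  expect_true("feat02" %in% eliminate_features(cohort, 0.99)$dropped)

  # monotone: higher threshold never drops more
  thresholds <- seq(0, 1, by = 0.1)
  n_dropped <- vapply(thresholds,
                      function(t) length(eliminate_features(cohort, t)$dropped),
                      numeric(1))
  expect_true(all(diff(n_dropped) <= 0))
})

test_that("imputer medians and modes follow the stated conventions", {
  cohort <- make_test_cohort(n_control = 3, n_case = 3, seed = 1,
                             n_features = 2)
  cohort$feat01 <- c(1, 2, 100, NA, NA, NA)
  cohort$feat02 <- c(1, 2, 3, 4, NA, NA)
  cohort$sex <- c("male", "male", "female", "male", "female", "female")

  model <- fit_imputer(cohort)
  expect_equal(model$medians[["feat01"]], 2)
  # even count: mean of the two central order statistics (sorting oracle)
  s <- sort(c(1, 2, 3, 4))
  expect_equal(model$medians[["feat02"]], (s[2] + s[3]) / 2)
  expect_equal(model$fitted_on_n, 6L)

  cohort$sex <- c("male", "male", "female", "male", "male", "male")
  expect_equal(fit_imputer(cohort)$modes$sex, "male")
  # tie broken lexicographically
  cohort$sex <- c("male", "male", "male", "female", "female", "female")
  expect_equal(fit_imputer(cohort)$modes$sex, "female")

  cohort$feat01 <- NA_real_
  expect_error(fit_imputer(cohort), "feat01")
})

test_that("apply_imputer completes tables without touching observed values", {
  cohort <- make_test_cohort(n_control = 40, n_case = 40, seed = 2,
                             n_features = 3)
  holed <- inject_missingness(cohort, c(feat01 = 0.3, feat02 = 0.2), seed = 3)
  model <- fit_imputer(holed)
  filled <- apply_imputer(model, holed)

  expect_false(anyNA(filled[, lab_features(filled)]))
  obs <- !is.na(holed$feat01)
  expect_identical(filled$feat01[obs], holed$feat01[obs])
  expect_true(all(filled$feat01[!obs] == model$medians[["feat01"]]))

  # idempotence and no-op on complete data
  expect_identical(apply_imputer(model, filled), filled)
  expect_identical(apply_imputer(model, cohort), cohort)

  extra <- holed
  extra$newfeat <- 1
  attr(extra, "lab_features") <- c(lab_features(holed), "newfeat")
  expect_error(apply_imputer(model, extra), "newfeat")
})

test_that("fold-fitted imputation cannot leak test-fold information", {
  cohort <- make_test_cohort(n_control = 40, n_case = 40, seed = 4,
                             n_features = 2)
  cohort <- inject_missingness(cohort, c(feat01 = 0.25), seed = 5)
  test_idx <- seq_len(20)
  train <- cohort[-test_idx, ]
  test <- cohort[test_idx, ]

  model <- fit_imputer(train)
  # fold-fitted median differs (stochastically) from the full-data median
  expect_false(model$medians[["feat01"]] ==
                 median(cohort$feat01, na.rm = TRUE) &&
               model$medians[["feat02"]] ==
                 median(cohort$feat02, na.rm = TRUE))

  # swapping a test-fold value never changes the fitted medians
  test2 <- test
  test2$feat01[1] <- 1e6
  expect_identical(fit_imputer(train)$medians, model$medians)
  # and held-out observed values pass through untouched
  filled <- apply_imputer(model, test2)
  expect_equal(filled$feat01[1], 1e6)
})

test_that("sex encoding uses the fixed female=0, male=1 convention", {
  cohort <- make_test_cohort(n_control = 5, n_case = 5, seed = 1)
  original <- cohort$sex
  enc <- encode_sex(cohort)
  expect_true(is.numeric(enc$sex))
  expect_identical(enc$sex, as.numeric(original == "male"))
  expect_identical(decode_sex(enc)$sex, original)

  cohort$sex[3] <- "unknown"
  expect_error(encode_sex(cohort), "row 3")

  allm <- cohort; allm$sex <- rep("male", 10)
  expect_true(all(encode_sex(allm)$sex == 1))
  allf <- cohort; allf$sex <- rep("female", 10)
  expect_true(all(encode_sex(allf)$sex == 0))
})

test_that("scaler standardizes with training statistics only", {
  cohort <- encode_sex(make_test_cohort(n_control = 60, n_case = 60, seed = 6,
                                        n_features = 3, delta = 2))
  train <- cohort[1:80, ]
  test <- cohort[81:120, ]
  model <- fit_scaler(train)
  strain <- apply_scaler(model, train)
  expect_lt(abs(mean(strain$feat01)), 1e-9)
  expect_lt(abs(sd(strain$feat01) - 1), 1e-9)

  # test-fold means are generally non-zero under train-only statistics
  stest <- apply_scaler(model, test)
  expect_gt(max(abs(vapply(lab_features(test),
                           function(f) mean(stest[[f]]), numeric(1)))), 1e-4)

  # constant training column maps to zeros
  const <- train; const$feat02 <- 7
  sconst <- apply_scaler(fit_scaler(const), const)
  expect_true(all(sconst$feat02 == 0))
})
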