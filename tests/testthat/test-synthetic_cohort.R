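test_that("builtin feature specs load with the published summary statistics", {
  specs <- load_feature_specs()
  expect_s3_class(specs, "feature_spec_tbl")
  expect_equal(nrow(specs), 45L)
  glu <- specs[specs$name == "Glucose", ]
  expect_equal(glu$control_mean, 93.312)
  expect_equal(glu$control_sd, 26.932)
  expect_equal(glu$case_mean, 83.039)
  expect_equal(glu$case_sd, 10.139)
  expect_true(all(specs$control_sd >= 0 & specs$case_sd >= 0))
  expect_false(any(duplicated(specs$name)))
})

test_that("feature spec parsing rejects malformed input", {
  empty <- tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_feature_specs(empty))

  header_only <- write_test_spec_csv(make_test_specs(1)[0, ])
  expect_error(load_feature_specs(header_only), "no rows")

  dup <- make_test_specs(2)
  dup$name <- c("A", "A")
  expect_error(load_feature_specs(write_test_spec_csv(dup)), "duplicate")

  bad <- make_test_specs(2)
  bad$control_mean <- c("1.0", "oops")
  expect_error(load_feature_specs(write_test_spec_csv(bad)), "row 2")

  roundtrip <- load_feature_specs(write_test_spec_csv(make_test_specs(3)))
  expect_equal(roundtrip$name, sprintf("feat%02d", 1:3))
})

test_that("generate_cohort produces the configured group structure", {
  specs <- load_feature_specs()
  cohort <- generate_cohort(cohort_config(n_control = 192, n_case = 203,
                                          seed = 1), specs)
  expect_equal(nrow(cohort), 395L)
  expect_equal(sum(cohort$group == "case"), 203L)
  expect_equal(sum(cohort$group == "control"), 192L)
  expect_setequal(lab_features(cohort), specs$name)
  expect_true(all(cohort$sex %in% c("male", "female")))
  # label balance exact
  expect_equal(mean(cohort$group == "case"), 203 / 395)
})

test_that("generation is deterministic given the seed", {
  a <- make_test_cohort(seed = 7)
  b <- make_test_cohort(seed = 7)
  expect_identical(a, b)
  c <- make_test_cohort(seed = 8)
  expect_false(identical(a, c))
  # byte-identical CSV output
  fa <- tempfile(); fb <- tempfile()
  write_cohort_csv(a, fa); write_cohort_csv(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("zero-variance specs give constant columns at the means", {
  specs <- make_test_specs(2, delta = 3, sd = 0)
  cohort <- generate_cohort(cohort_config(n_control = 5, n_case = 5, seed = 1),
                            specs)
  expect_true(all(cohort$feat01[cohort$group == "control"] == 50))
  expect_true(all(cohort$feat01[cohort$group == "case"] == 53))
})

test_that("marginals recover configured parameters at large n", {
  # law-of-large-numbers check at n_case = 50,000 against configured values
  specs <- make_test_specs(3, delta = 5, sd = 2, mean = 100)
  cohort <- generate_cohort(cohort_config(n_control = 4, n_case = 50000,
                                          seed = 42), specs)
  case_rows <- cohort$group == "case"
  for (f in lab_features(cohort)) {
    x <- cohort[[f]][case_rows]
    expect_close(mean(x), 105, tol = 3 * 2 / sqrt(50000))
    expect_close(sd(x), 2, tol = 3 * 2 / sqrt(50000))
  }
})

test_that("truncation enforces the physiological floor", {
  specs <- make_test_specs(2, mean = 0.5, sd = 1)  # heavy mass below 0
  cohort <- generate_cohort(cohort_config(n_control = 500, n_case = 500,
                                          seed = 3), specs)
  for (f in lab_features(cohort)) expect_true(all(cohort[[f]] >= 0))
})

test_that("shared latent factor induces positive between-feature correlation", {
  base <- make_test_cohort(n_control = 400, n_case = 400, seed = 5,
                           correlation = 0)
  cor0 <- cor(base$feat01[base$group == "case"],
              base$feat02[base$group == "case"])
  corr <- make_test_cohort(n_control = 400, n_case = 400, seed = 5,
                           correlation = 0.5)
  cor5 <- cor(corr$feat01[corr$group == "case"],
              corr$feat02[corr$group == "case"])
  expect_lt(abs(cor0), 0.15)
  expect_gt(cor5, 0.3)  # loading sqrt(.5) each => cor = 0.5
})

test_that("inject_missingness is MCAR with the requested rates", {
  cohort <- make_test_cohort(n_control = 200, n_case = 195, seed = 1)

  unchanged <- inject_missingness(cohort, c(feat01 = 0), seed = 1)
  expect_identical(unchanged, cohort)

  all_gone <- inject_missingness(cohort, c(feat02 = 1), seed = 1)
  expect_true(all(is.na(all_gone$feat02)))
  expect_false(anyNA(all_gone$feat01))

  # blanked count within the central 99% binomial interval
  hit <- inject_missingness(cohort, c(feat03 = 0.2), seed = 9)
  n_blank <- sum(is.na(hit$feat03))
  expect_gte(n_blank, qbinom(0.005, 395, 0.2))
  expect_lte(n_blank, qbinom(0.995, 395, 0.2))

  # demographics are never blanked
  expect_false(anyNA(hit$group) || anyNA(hit$sex) || anyNA(hit$age))

  expect_error(inject_missingness(cohort, c(nope = 0.5), seed = 1), "unknown")
  expect_error(inject_missingness(cohort, c(feat01 = 1.2), seed = 1))
})

test_that("spec-level missing rates are applied by the generator", {
  specs <- make_test_specs(2)
  specs$missing_rate <- c(0.5, 0)
  cohort <- generate_cohort(cohort_config(n_control = 100, n_case = 100,
                                          seed = 2), specs)
  expect_gt(mean(is.na(cohort$feat01)), 0.35)
  expect_false(anyNA(cohort$feat02))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_control = 0), "positive")
  expect_error(cohort_config(n_control = 1, n_case = 1), "at least 4")
  expect_error(cohort_config(correlation = 1), "correlation")
  expect_error(cohort_config(male_fraction_case = 1.5))
  expect_error(generate_cohort(cohort_config(), make_test_specs(1)[0, ]))
})
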