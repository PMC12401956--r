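#' Configuration for synthetic cohort generation
#'
#' Defaults reproduce the reference study population: 192 controls and 203
#' cases (395 subjects), control ages 28.3 (SD 10.7) years and case ages 28.7
#' (SD 3.9) years, male fractions 130/192 and 154/203. `correlation` is the
#' loading of a single shared standard-normal latent factor added to every
#' standardized lab draw (default 0, i.e. independent analytes).
#'
#' @param n_control,n_case positive integer group sizes.
#' @param seed integer seed controlling all draws.
#' @param correlation shared-latent-factor loading in `[0, 1)`.
#' @param age_control_mean,age_control_sd,age_case_mean,age_case_sd per-group
#'   Gaussian age parameters (years).
#' @param male_fraction_control,male_fraction_case Bernoulli male probability
#'   per group.
#' @param age_lower_bound truncation floor for ages (years).
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_case
cohort_config <- function(n_control = 192L, n_case = 203L, seed = 0L,
                          correlation = 0,
                          age_control_mean = 28.3, age_control_sd = 10.7,
                          age_case_mean = 28.7, age_case_sd = 3.9,
                          male_fraction_control = 130 / 192,
                          male_fraction_case = 154 / 203,
                          age_lower_bound = 0) {
  if (!is.numeric(n_control) || n_control < 1 || n_control != round(n_control))
    stop("`n_control` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_case) || n_case < 1 || n_case != round(n_case))
    stop("`n_case` must be a positive integer", call. = FALSE)
  if (n_control + n_case < 4)
    stop("total cohort size must be at least 4", call. = FALSE)
  assert_scalar_in(correlation, 0, 1, "correlation", right_open = TRUE)
  assert_scalar_in(male_fraction_control, 0, 1, "male_fraction_control")
  assert_scalar_in(male_fraction_case, 0, 1, "male_fraction_case")
  if (age_control_sd < 0 || age_case_sd < 0)
    stop("age standard deviations must be non-negative", call. = FALSE)
  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    seed = as.integer(seed), correlation = correlation,
    age_control_mean = age_control_mean, age_control_sd = age_control_sd,
    age_case_mean = age_case_mean, age_case_sd = age_case_sd,
    male_fraction_control = male_fraction_control,
    male_fraction_case = male_fraction_case,
    age_lower_bound = age_lower_bound
  ), class = "cohort_config")
}

# Gaussian draws truncated below at `lb` by redraw; `shared` is the latent
# factor contribution already in standard units. sd == 0 yields a constant.
#' @noRd
truncated_normal <- function(n, mean, sd, lb, shared, loading) {
  if (sd == 0) return(rep(mean, n))
  resid <- sqrt(1 - loading^2)
  x <- mean + sd * (loading * shared + resid * rnorm(n))
  if (!is.finite(lb)) return(x)
  for (iter in seq_len(1000L)) {
    below <- which(x < lb)
    if (!length(below)) break
    x[below] <- mean + sd * (loading * shared[below] + resid * rnorm(length(below)))
  }
  pmax(x, lb)
}

#' Generate a synthetic case-control cohort
#'
#' Draws each lab value from the configured per-group Gaussian, truncated
#' below at the analyte's physiological floor (re-draw), with an optional
#' shared latent factor inducing positive between-analyte correlation. Sex is
#' Bernoulli per group, age Gaussian per group. Any non-zero `missing_rate`
#' in the specs is applied afterwards via [inject_missingness()]. The result
#' is fully determined by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param specs a feature-spec table from [load_feature_specs()].
#' @return A `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `group` (`"control"`/`"case"`), `sex` (`"male"`/`"female"`), `age`, and
#'   one numeric column per analyte. The analyte names are recorded in
#'   `attr(, "lab_features")`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1), load_feature_specs())
#' nrow(cohort)  # 395
generate_cohort <- function(config, specs) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config", call. = FALSE)
  if (!inherits(specs, "feature_spec_tbl")) validate_feature_specs(specs)
  if (nrow(specs) == 0L) stop("`specs` must be non-empty", call. = FALSE)

  n_ctrl <- config$n_control
  n_case <- config$n_case
  n <- n_ctrl + n_case
  group <- c(rep("control", n_ctrl), rep("case", n_case))
  loading <- sqrt(config$correlation)

  with_seed(config$seed, {
    sex <- c(
      ifelse(rbinom(n_ctrl, 1L, config$male_fraction_control) == 1L, "male", "female"),
      ifelse(rbinom(n_case, 1L, config$male_fraction_case) == 1L, "male", "female")
    )
    shared <- rnorm(n)  # latent factor, one per subject
    age <- numeric(n)
    age[seq_len(n_ctrl)] <- truncated_normal(
      n_ctrl, config$age_control_mean, config$age_control_sd,
      config$age_lower_bound, shared[seq_len(n_ctrl)], 0)
    age[n_ctrl + seq_len(n_case)] <- truncated_normal(
      n_case, config$age_case_mean, config$age_case_sd,
      config$age_lower_bound, shared[n_ctrl + seq_len(n_case)], 0)

    labs <- matrix(NA_real_, nrow = n, ncol = nrow(specs),
                   dimnames = list(NULL, specs$name))
    is_ctrl <- group == "control"
    for (j in seq_len(nrow(specs))) {
      s <- specs[j, ]
      labs[is_ctrl, j] <- truncated_normal(
        n_ctrl, s$control_mean, s$control_sd, s$lower_bound,
        shared[is_ctrl], loading)
      labs[!is_ctrl, j] <- truncated_normal(
        n_case, s$case_mean, s$case_sd, s$lower_bound,
        shared[!is_ctrl], loading)
    }

    tab <- data.frame(
      subject_id = sprintf("%s_%04d", ifelse(is_ctrl, "ctrl", "case"),
                           c(seq_len(n_ctrl), seq_len(n_case))),
      group = group, sex = sex, age = age,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    tab <- cbind(tab, as.data.frame(labs, check.names = FALSE))
    tab <- as_cohort_table(tab, lab_features = specs$name)

    rates <- setNames(specs$missing_rate, specs$name)
    if (any(rates > 0))
      tab <- inject_missingness(tab, rates[rates > 0],
                                seed = derive_seed(config$seed, "missingness"))
    tab
  })
}

#' @noRd
as_cohort_table <- function(df, lab_features) {
  attr(df, "lab_features") <- lab_features
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Names of the lab analyte columns of a cohort table
#' @param table a `cohort_table`.
#' @return Character vector of analyte column names.
#' @export
lab_features <- function(table) {
  lf <- attr(table, "lab_features")
  lf %||% setdiff(names(table), c("subject_id", "group", "sex", "age"))
}

#' Blank cohort cells completely at random
#'
#' Each targeted cell is independently set to missing with its feature's
#' rate (MCAR). `group`, `sex` and `age` are never blanked here.
#'
#' @param table a `cohort_table`.
#' @param rates named numeric vector or list, feature name -> rate in `[0, 1]`.
#' @param seed integer seed.
#' @return The cohort table with missing cells injected.
#' @export
inject_missingness <- function(table, rates, seed = 0L) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("`rates` must be named by feature", call. = FALSE)
  unknown <- setdiff(names(rates), lab_features(table))
  if (length(unknown))
    stop("unknown feature in `rates`: ", unknown[1], call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    for (f in names(rates)) {
      if (rates[[f]] == 0) next
      hit <- runif(nrow(table)) < rates[[f]]
      table[[f]][hit] <- NA_real_
    }
    table
  })
}

#' Read / write cohort CSV files
#'
#' The on-disk format is a comma-separated UTF-8 table with header
#' `subject_id,group,sex,age,<analyte...>`, one subject per row, missing lab
#' values as empty cells. Numbers are written with 17 significant digits so
#' that write -> read round-trips reproduce the in-memory doubles exactly.
#'
#' @param path file path.
#' @param table a `cohort_table`.
#' @return `read_cohort_csv` returns a `cohort_table`; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  required <- c("subject_id", "group", "sex", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!raw$group %in% c("case", "control"))
  if (length(bad))
    stop(sprintf("row %d: unknown group token '%s'", bad[1], raw$group[bad[1]]),
         call. = FALSE)
  bad <- which(!raw$sex %in% c("male", "female") & nzchar(raw$sex))
  if (length(bad))
    stop(sprintf("row %d: unknown sex token '%s'", bad[1], raw$sex[bad[1]]),
         call. = FALSE)
  labs <- setdiff(names(raw), required)
  out <- data.frame(subject_id = raw$subject_id, group = raw$group,
                    sex = ifelse(nzchar(raw$sex), raw$sex, NA_character_),
                    age = as.numeric(raw$age),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (f in labs) {
    x <- raw[[f]]
    x[!nzchar(x)] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop(sprintf("row %d: non-numeric value '%s' in column '%s'",
                   bad[1], x[bad[1]], f), call. = FALSE)
    out[[f]] <- v
  }
  as_cohort_table(out, lab_features = labs)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(subject_id = table$subject_id, group = table$group,
                    sex = as.character(table$sex),
                    age = fmt(table$age),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (f in lab_features(table)) out[[f]] <- fmt(table[[f]])
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
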