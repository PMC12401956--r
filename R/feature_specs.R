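#' Per-analyte generative parameters
#'
#' A feature-spec table holds, for each laboratory analyte, the per-group
#' (control / case) mean and standard deviation used by the cohort generator,
#' a physiological lower bound (lab analytes cannot be negative, so the
#' default floor is 0), and an MCAR missingness rate.
#'
#' The packaged builtin set covers 45 routine haematology and clinical
#' chemistry analytes (complete blood count indices, leukocyte
#' subpopulations, electrolytes, liver enzymes, lipids, renal markers) with
#' per-group summary statistics typical of a schizophrenia inpatient arm
#' versus age-matched controls.
#'
#' @param source Either the string `"builtin"` for the packaged analyte set,
#'   or a path to a CSV file with header
#'   `name,unit,control_mean,control_sd,case_mean,case_sd,lower_bound,missing_rate`.
#'   An empty `lower_bound` cell defaults to 0; an empty `missing_rate` cell
#'   defaults to 0.
#' @return A `data.frame` of class `feature_spec_tbl`, one row per analyte,
#'   in file order.
#' @export
#' @examples
#' specs <- load_feature_specs()
#' nrow(specs)
#' specs[specs$name == "Glucose", ]
load_feature_specs <- function(source = "builtin") {
  stopifnot(is.character(source), length(source) == 1L)
  path <- if (identical(source, "builtin")) {
    system.file("extdata", "lab_feature_specs.csv", package = "wolfscreen",
                mustWork = TRUE)
  } else {
    if (!file.exists(source)) stop("feature spec file not found: ", source,
                                   call. = FALSE)
    source
  }
  raw <- tryCatch(
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = "character"),
    error = function(e) stop("cannot parse feature spec file: ",
                             conditionMessage(e), call. = FALSE))
  required <- c("name", "unit", "control_mean", "control_sd", "case_mean",
                "case_sd", "lower_bound", "missing_rate")
  if (nrow(raw) == 0L) stop("feature spec file has no rows", call. = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("feature spec file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num <- function(col, default = NA_real_) {
    x <- raw[[col]]
    x[!nzchar(trimws(x))] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
      stop(sprintf("feature spec row %d ('%s'): column '%s' is not numeric",
                   bad[1], raw$name[bad[1]], col), call. = FALSE)
    out[is.na(out)] <- default
    out
  }
  specs <- data.frame(
    name = trimws(raw$name),
    unit = raw$unit,
    control_mean = num("control_mean"),
    control_sd = num("control_sd"),
    case_mean = num("case_mean"),
    case_sd = num("case_sd"),
    lower_bound = num("lower_bound", default = 0),
    missing_rate = num("missing_rate", default = 0),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  validate_feature_specs(specs)
  class(specs) <- c("feature_spec_tbl", "data.frame")
  specs
}

#' @noRd
validate_feature_specs <- function(specs) {
  for (col in c("control_mean", "control_sd", "case_mean", "case_sd")) {
    bad <- which(!is.finite(specs[[col]]))
    if (length(bad))
      stop(sprintf("feature spec row %d ('%s'): missing or non-finite '%s'",
                   bad[1], specs$name[bad[1]], col), call. = FALSE)
  }
  if (any(!nzchar(specs$name)))
    stop("feature spec has an empty name", call. = FALSE)
  dup <- specs$name[duplicated(specs$name)]
  if (length(dup))
    stop("duplicate feature name in spec table: ", dup[1], call. = FALSE)
  if (any(specs$control_sd < 0) || any(specs$case_sd < 0))
    stop("feature spec standard deviations must be non-negative", call. = FALSE)
  if (any(specs$missing_rate < 0 | specs$missing_rate > 1))
    stop("feature spec missing_rate must lie in [0, 1]", call. = FALSE)
  invisible(specs)
}

#' Demographic constants of the reference case-control cohort
#'
#' Group sizes, sex counts and per-group age summaries describing the study
#' population the default generator emulates: 192 controls (130 male) aged
#' 28.3 (SD 10.7) years and 203 schizophrenia cases (154 male) aged 28.7
#' (SD 3.9) years.
#'
#' @return A list with elements `n_control`, `n_case`, `male_control`,
#'   `male_case`, `age_control` (`mean`, `sd`), `age_case` (`mean`, `sd`).
#' @export
#' @examples
#' cohort_demographics()$n_case
cohort_demographics <- function() {
  list(
    n_control = 192L, n_case = 203L,
    male_control = 130L, male_case = 154L,
    age_control = c(mean = 28.3, sd = 10.7),
    age_case = c(mean = 28.7, sd = 3.9)
  )
}
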