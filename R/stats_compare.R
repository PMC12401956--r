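#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. `welch_t()` consumes raw observations;
#' `welch_t_summary()` consumes the groups' summary statistics — the two
#' entry points agree exactly when the summaries are computed from the raw
#' data. Set `var_equal = TRUE` for the pooled-variance (Student) variant.
#'
#' @param values_a,values_b numeric vectors with at least 2 observed values
#'   each (missing values dropped).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics.
#' @param var_equal use pooled variance instead of Welch.
#' @return A list with `statistic`, `df`, `p`.
#' @export
#' @examples
#' welch_t_summary(28.3, 10.7, 192, 28.7, 3.9, 203)
welch_t <- function(values_a, values_b, var_equal = FALSE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observed values", call. = FALSE)
  welch_t_summary(mean(a), stats::sd(a), length(a),
                  mean(b), stats::sd(b), length(b), var_equal = var_equal)
}

#' @rdname welch_t
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                            var_equal = FALSE) {
  if (min(n_a, n_b) < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  if (se == 0) {
    t <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
  } else {
    t <- (mean_a - mean_b) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p = p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (the default; set `correct = TRUE` for the
#' Yates-corrected variant), df = 1, two-sided p.
#'
#' @param a,b,c,d cell counts: rows are groups, columns are categories
#'   (`a`,`b` = group 1; `c`,`d` = group 2).
#' @param correct apply the Yates continuity correction.
#' @return A list with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square_2x2(130, 62, 154, 49)
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0)
    stop("zero margin in 2x2 table", call. = FALSE)
  adj <- if (correct) pmin(abs(a * d - b * c), n / 2) else abs(a * d - b * c)
  stat <- n * adj^2 / (as.numeric(r1) * r2 * c1 * c2)
  list(statistic = stat, df = 1, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-feature case-control comparison table
#'
#' One row per lab analyte (optionally age), giving observed per-group
#' means/SDs, the two-sample test statistic and p-value, sorted by p
#' ascending (stable: equal p keeps input order), with a significance flag
#' at p < 0.05.
#'
#' @param cohort a `cohort_table` containing both groups.
#' @param include_age also test the age column.
#' @param var_equal pooled-variance instead of Welch.
#' @param alpha significance level for the flag.
#' @return A `data.frame` with columns `feature`, `control_mean`,
#'   `control_sd`, `case_mean`, `case_sd`, `statistic`, `df`, `p`,
#'   `significant`.
#' @export
comparison_table <- function(cohort, include_age = FALSE, var_equal = FALSE,
                             alpha = 0.05) {
  groups <- unique(cohort$group)
  if (!all(c("case", "control") %in% groups))
    stop("cohort must contain both a case and a control group", call. = FALSE)
  feats <- lab_features(cohort)
  if (include_age) feats <- c(feats, "age")
  is_ctrl <- cohort$group == "control"
  rows <- lapply(feats, function(f) {
    a <- cohort[[f]][is_ctrl]
    b <- cohort[[f]][!is_ctrl]
    tt <- welch_t(a, b, var_equal = var_equal)
    data.frame(feature = f,
               control_mean = mean(a, na.rm = TRUE),
               control_sd = stats::sd(a[!is.na(a)]),
               case_mean = mean(b, na.rm = TRUE),
               case_sd = stats::sd(b[!is.na(b)]),
               statistic = tt$statistic, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]  # order() is stable on ties
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Display-format a p-value column
#'
#' Four decimals, floored at 0.0001 (values below are shown as
#' `"<0.0001"`), matching the conventional clinical-table style. Full
#' precision is kept in the numeric column; this is presentation only.
#'
#' @param p numeric p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
}
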