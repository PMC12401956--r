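#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage seed from a global seed
#'
#' Fans one user-facing seed out to per-stage seeds so that every stochastic
#' stage (simulation, fold assignment, selection, model fitting) is
#' independently reproducible. The derivation is a fixed affine hash of the
#' stage label, kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"simulate"`, `"gwo"`.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' @noRd
assert_scalar_in <- function(x, lo, hi, what, right_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo &&
    (if (right_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single number in [%s, %s%s", what, lo,
                        hi, if (right_open) ")" else "]"), call. = FALSE)
  invisible(x)
}
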