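#' @keywords internal
"_PACKAGE"

# Run code under a local RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package funnel through this so that a
# given (seed, parameters) pair regenerates byte-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' A fixed counter scheme fans one global seed out to named pipeline
#' stages, so each stage is individually reproducible and no two stages
#' share an RNG stream. The result stays in the 32-bit signed range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Signed angular difference a - b wrapped to (-180, 180] degrees.
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Z-score a vector; constant input maps to all zeros (degenerate guard).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
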