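# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random
#' state afterwards, so no function in the package touches global RNG
#' state as a side effect.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

## Modulus that always returns a value in [0, m)
posmod <- function(x, m) ((x %% m) + m) %% m

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stopf("%s must be finite numeric", name)
  invisible(x)
}

## Clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
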