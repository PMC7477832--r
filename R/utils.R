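# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic steps in the package (fold shuffling, weight initialization,
#' mini-batch ordering, synthetic data generation) run through this helper so
#' that results are reproducible from a single integer seed and calling package
#' functions never perturbs the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive independent sub-seeds from one user seed (seed, seed+1, ...),
# kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + offset) %% 2147483647
  as.integer(s)
}

stop_mosae <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_mosae(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_mosae(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_mosae(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  as.numeric(x)
}
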