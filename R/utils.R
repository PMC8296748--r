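# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' then restores the previous RNG state so callers' random streams are
#' unaffected. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# numerically safe sigmoid
sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# softmax of a vector, max-subtracted for stability
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
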