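# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit. All stochastic operations in the
#' package route their `seed` argument through this helper so that results
#' are pure functions of their inputs.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

assert_nonneg_matrix <- function(M, name = "M") {
  abort_if(!is.matrix(M) || !is.numeric(M), "%s must be a numeric matrix", name)
  abort_if(anyNA(M), "%s contains missing values", name)
  abort_if(any(M < 0), "%s has negative entries; a nonnegative matrix is required", name)
  invisible(M)
}

# Round half away from zero (the usual "half-up" presentation convention;
# base R round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
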