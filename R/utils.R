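`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state
#' afterwards.  All stochastic operations in the package route through this
#' so that a single integer seed fixes a result.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic, collision-resistant seed derivation staying inside the
#' 32-bit integer range R requires; used to give every subject, run and
#' training repeat its own reproducible stream.
#'
#' @param seed base integer seed.
#' @param index positive stream index.
#' @return an integer-valued seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(index)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
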