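# Internal helpers shared across modules.

#' @importFrom stats cor rgamma rlnorm rpois runif setNames complete.cases sd
#' @importFrom utils combn head
NULL

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards (a `NULL` seed leaves the stream untouched). All
#' stochastic operations in the package funnel through this, so results
#' are reproducible without disturbing the session's random stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a deterministic per-step seed from a master seed
#'
#' A fixed affine map modulo `2^31 - 1`, giving every named step of a
#' pipeline its own reproducible random substream.
#'
#' @param seed Integer master seed.
#' @param step Integer step index.
#' @return Integer seed below `2^31`.
#' @export
derive_seed <- function(seed, step) {
  as.integer((as.double(seed) * 48271 + step * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
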