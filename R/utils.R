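#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the state on exit, so seeded primitives never perturb the
#' surrounding random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item child seed, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- as.numeric(c(seed, ...))
  h <- 0
  for (p in parts) h <- (h * 7919 + (p %% 104729) + 1) %% 2147483563
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
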