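#' @importFrom stats rnorm runif predict sd var qnorm
#' @importFrom methods new validObject is slot
NULL

PAIN_LEVELS <- c("NoPain", "LowPain", "HighPain")

painFactor <- function(x) factor(x, levels = PAIN_LEVELS)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so library code never perturbs user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Deterministic sub-seed derivation; stays below 2^31 - 1.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
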