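#' @importFrom rlang .data
#' @importFrom stats median setNames rnorm runif rbinom rpois p.adjust
NULL

# Structured stage logging: one line per event on stderr, so excluded
# samples/pairs are never dropped silently.
eg_log <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s: %s", level, stage, msg))
  invisible(NULL)
}

#' Derive independent child seeds from one master seed
#'
#' A single cohort or pipeline seed fans out to one child seed per random
#' stream (lineages, carriage, dropout, abundances, ...) so that each
#' sub-component is independently reproducible.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a temporary seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the previous
#' RNG state, so seeded sub-computations do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
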