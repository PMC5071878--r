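#' @importFrom MASS ginv
#' @importFrom stats rnorm runif rbinom sd
#' @importFrom utils write.table
NULL

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
# All stochastic code in the package funnels through this so that a seed given
# in a config fully determines the result without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Moore-Penrose pseudo-inverse. Delegates to MASS::ginv but guards the
# all-zero block, for which the convention pinv(0) = 0 keeps degenerate
# factor updates well defined.
pinv <- function(A) {
  if (all(A == 0)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  MASS::ginv(A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ri <- function(...) stop(..., call. = FALSE)
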