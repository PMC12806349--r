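## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
## All user-facing stochastic operations funnel through this so that they are
## deterministic given their `seed` argument and side-effect free on .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }
  force(expr)
}

## Derive a stream of distinct child seeds from one parent seed, so that
## independent stages (e.g. segment placement vs. Poisson sampling) do not
## share RNG streams. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
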