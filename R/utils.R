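## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state. All stochastic operations in the package funnel through this so
## that a given (function, seed) pair is bit-reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
                  name, x, lower, upper))
  }
  invisible(x)
}

## Log-spaced integer lag grid between lo and hi (inclusive, unique).
log_lags <- function(lo, hi, n = 60L) {
  if (hi <= lo) return(lo)
  unique(round(exp(seq(log(lo), log(hi), length.out = n))))
}
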