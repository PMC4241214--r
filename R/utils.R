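## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards: generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

## Quartile-based IQR with the linear-interpolation (type 7) convention,
## stated explicitly because precision summaries depend on it.
iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  q[2] - q[1]
}
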