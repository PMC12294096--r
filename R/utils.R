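# Internal helpers: argument checking and seeded randomness that does not
# leak into (or depend on) the caller's global RNG state.

stop_if_not_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                               finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so simulation is reproducible without touching global state.
with_seed <- function(seed, expr) {
  stop_if_not_scalar(seed, "seed")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
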