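# internal helpers

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream" (no save/restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic substream seed for block length m, realization r.
# Kept < 2^31 - 1; exact in double arithmetic (products stay below 2^53).
substream_seed <- function(seed, m, r) {
  ((seed %% 2147483647) * 48271 + m * 1299709 + r * 15485863) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
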