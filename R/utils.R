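`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All stochastic generators in the package route through
# this so that a fixed seed gives byte-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed below 2^31 from a base seed.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * stream) %% 2147483629
}
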