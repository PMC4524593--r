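# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded helpers do not perturb the
# ambient random stream. With seed = NULL the ambient stream is used as-is.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stream of well-separated child seeds from one parent seed,
# staying within the 32-bit integer range.
derive_seeds <- function(seed, n, stream = 0L) {
  (as.double(seed) * 48271 + stream * 7919 + seq_len(n) * 104729) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
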