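# Internal helpers: seeded substreams and weighted sampling.

.datatable.aware <- TRUE

# Derive a reproducible integer seed for a named substream of a master seed.
# Streams ("emission", "energy", "timing", "background", ...) make paired
# simulations possible: two runs sharing the emission stream but differing
# elsewhere see identical emission geometry.
substream_seed <- function(master, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 1000003L
  as.integer((as.double(master) * 2654435L + h * 97L) %% 2147483629)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# O(n log m) categorical sampling with replacement (base R's sample() with a
# long prob vector is too slow for millions of draws).
sample_weighted <- function(n, weights) {
  cw <- cumsum(as.double(weights))
  tot <- cw[length(cw)]
  stopifnot(tot > 0)
  findInterval(runif(n) * tot, cw) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
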