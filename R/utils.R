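`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness goes through this so that (seed, parameters)
# regenerate outputs bit-identically.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed < 2^31 from a parent seed and a stream index.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

# Polynomial rolling hash (mod 2^31-1) of a character vector, hex string.
# Used to stamp pipeline outputs with a config fingerprint without a
# digest dependency; not cryptographic.
content_hash <- function(x) {
  bytes <- as.numeric(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}
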