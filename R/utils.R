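# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character string (FNV-style polynomial).
# Used to derive named substream seeds so that adding a new stochastic
# component to a generator never shifts the draws of existing ones.
.stringHash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  h
}

# Substream seed derived from a top-level seed and a stream name.
# Stays strictly below 2^31 - 1 (R's set.seed takes a 32-bit integer).
.subSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(((abs(seed) %% 2147483629) * 69069 + .stringHash(name)) %% 2147483629)
}

# Evaluate expr under a named substream seed, restoring the caller's RNG
# state afterwards so generators do not perturb user code.
.withSubstream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.subSeed(seed, name))
  expr
}

# Configuration error naming the offending field.
.configError <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# Deterministic 32-bit content hash (djb2 variant), returned as 8 hex digits;
# used for the pipeline manifest (config and output fingerprints).
.textHash <- function(txt) {
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}
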