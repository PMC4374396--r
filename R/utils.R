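# Internal helpers shared across modules.

# Deterministic 32-bit polynomial hash of a string, returned as hex.
# Used to label internal nodes from their sorted leaf sets so branch
# identifiers are stable across runs and across tree re-orderings.
str_hash <- function(x) {
  h <- 0
  for (ci in utf8ToInt(x)) h <- (h * 131 + ci) %% 2147483647
  sprintf("%08x", h)
}

# Derive a per-stage seed from a master seed so independent pipeline
# stages do not share RNG streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- str_hash(paste0("famshift:", stage))
  as.integer((abs(seed) * 48271 + strtoi(substr(h, 1, 7), 16L)) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL,
# restoring the caller's RNG state afterwards; otherwise use the
# current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

is_count <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == round(x))
}
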