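# Internal helpers shared across modules.

# Deterministic substream seed from one global seed and a string key.
# Keeps every generator reproducible from a single integer while decoupling
# the random streams of independent stages. Result stays within 32-bit range.
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 99991L
  as.integer((abs(as.integer(seed)) %% 21470L) * 99991L + h)
}

# Evaluate expr under a local RNG seeded deterministically; global RNG state
# is untouched.
with_substream <- function(seed, key, expr) {
  withr::with_seed(substream_seed(seed, key), expr)
}

# Tiny xor/multiply content hash (hex string) used for run manifests. Not
# cryptographic; only needs to detect config/input changes deterministically.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- (h * 31 + b + 1) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Random DNA string of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_conjseq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "conjseq_error"))
}
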