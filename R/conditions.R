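# Structured condition classes used across the package so callers can
# distinguish data problems from usage problems programmatically.

dp_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "divpart_error")))
}

alignment_error <- function(msg, ...) dp_abort("alignment_error", msg, ...)
metadata_error  <- function(msg, ...) dp_abort("metadata_error", msg, ...)
parse_error     <- function(msg, ...) dp_abort("parse_error", msg, ...)
data_error      <- function(msg, ...) dp_abort("data_error", msg, ...)
key_error       <- function(msg, ...) dp_abort("key_error", msg, ...)
config_error    <- function(msg, ...) dp_abort("config_error", msg, ...)

# Deterministic 32-bit string hash (djb2), used to derive per-group RNG
# substreams from a single top-level seed.
hash_string <- function(x) {
  h <- 5381
  for (k in utf8ToInt(as.character(x))) h <- (h * 33 + k) %% 2147483647
  as.integer(h)
}

substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + as.numeric(hash_string(id))) %% 2147483647)
}
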