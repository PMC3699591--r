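# Deterministic random substreams.
#
# Every stochastic stage derives its own seed from the user seed plus a text
# tag naming what the stream is for (e.g. "posterior/<sample_id>"). Streams
# are therefore keyed to sample identity, never to column position, so
# permuting rows or columns of the input cannot change any result.

# 32-bit FNV-1a over the UTF-8 bytes of "<seed>/<tag>", reduced to a valid
# set.seed() value. Arithmetic is done in doubles; the multiply is split into
# 16-bit halves so no intermediate exceeds 2^53.
substream_seed <- function(seed, tag) {
  bytes <- utf8ToInt(enc2utf8(paste0(format(seed, scientific = FALSE), "/", tag)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256L))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483629 + 1)
}

# Evaluate `expr` under the substream for `tag`, or directly off the session
# RNG when no seed is given.
with_stream <- function(seed, tag, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(substream_seed(seed, tag), expr)
}

# Condition streams are keyed on the sorted sample-id set, so swapping the
# two condition labels (or reordering samples) reuses identical streams.
condition_tag <- function(sample_ids) paste(sort(sample_ids), collapse = "\036")
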