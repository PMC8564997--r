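# Deterministic named substreams: every source of randomness in a simulation
# derives its own seed from the master seed plus a purpose tag, so any stage
# can be re-drawn in isolation and a whole run is reproducible from the
# config alone.

# 32-bit FNV-1a over the tag string, folded with the master seed; kept in
# [1, 2^31 - 2] so it is always a valid set.seed() argument.
.substream_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(tag)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

# Evaluate expr under a substream seed, restoring the caller's RNG state.
.with_substream <- function(seed, tags, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(do.call(.substream_seed, c(list(seed), as.list(tags))))
  expr
}
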