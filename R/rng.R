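## Named RNG substreams: each generator output draws from a seed derived from
## (user seed, substream label), so adding one output type never perturbs the
## randomness of another, and every generator is deterministic for a fixed
## seed without touching the caller's RNG state.

substream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 48271 + h) %% 2147480009)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
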