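## Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## desk genome used across modules (deterministic)
test_genome <- function() {
  if (is.null(.fixture_env$genome))
    .fixture_env$genome <- generate_genome(seed = 42)
  .fixture_env$genome
}

## small genome without sequence for fast structural tests
small_genome <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_genome(list(
      chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), n_genes = 40,
      with_sequence = FALSE), seed = 11)
  }
  .fixture_env$small
}

## one-chromosome track from a plain numeric vector
vec_track <- function(v, bin_size = 1000, chrom = "chr1", ...) {
  signal_track(setNames(list(v), chrom), bin_size, ...)
}

uniform_track <- function(value, chrom_lengths, bin_size = 100) {
  values <- lapply(names(chrom_lengths), function(chrom)
    rep(value, ceiling(chrom_lengths[[chrom]] / bin_size)))
  names(values) <- names(chrom_lengths)
  signal_track(values, bin_size, chrom_lengths = chrom_lengths)
}
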