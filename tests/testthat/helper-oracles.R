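## Independent reference implementations used to cross-check the package.

## Brute-force domain caller: expand qualifying bins to intervals, then merge
## any two intervals whose end-to-end gap is <= merge_gap until fixpoint.
oracle_call_domains <- function(values, bin_size, threshold = 3,
                                merge_gap = 2 * bin_size) {
  qual <- which(values >= threshold)
  if (!length(qual)) return(matrix(numeric(), ncol = 2))
  ivs <- cbind((qual - 1) * bin_size, qual * bin_size)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(ivs)) {
      j <- i + 1
      while (j <= nrow(ivs)) {
        gap <- max(ivs[i, 1], ivs[j, 1]) - min(ivs[i, 2], ivs[j, 2])
        if (gap <= merge_gap) {
          ivs[i, ] <- c(min(ivs[i, 1], ivs[j, 1]), max(ivs[i, 2], ivs[j, 2]))
          ivs <- ivs[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  ivs[order(ivs[, 1]), , drop = FALSE]
}

## Per-base expansion oracle for bedGraph binning: lay records on a per-base
## vector, then sum each bin and divide by bin_size.
oracle_bin_records <- function(records, bin_size, genome_len) {
  base <- numeric(genome_len)
  for (i in seq_len(nrow(records)))
    base[(records$start[i] + 1):records$end[i]] <- records$value[i]
  nb <- ceiling(genome_len / bin_size)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * bin_size + 1
    hi <- min(b * bin_size, genome_len)
    sum(base[lo:hi]) / bin_size
  }, numeric(1))
}

## Exhaustive 2-means oracle for small matrices: best within-cluster SS over
## all 2-partitions.
oracle_best_2partition <- function(mat) {
  n <- nrow(mat)
  best <- NULL
  best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix row 1 in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ss <- 0
    for (cl in 1:2) {
      rows <- mat[lab == cl, , drop = FALSE]
      if (nrow(rows))
        ss <- ss + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- lab }
  }
  list(labels = best, ss = best_ss)
}

## Spearman via the rank-difference formula (no ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## Per-base metagene oracle for a single plus-strand gene.
oracle_gene_profile <- function(track, chrom, gstart, gend, body_bins,
                                flank, flank_bins) {
  per_base <- function(lo, hi) {
    pos <- lo:(hi - 1)
    vapply(pos, function(p) track_region_mean(track, chrom, p, p + 1),
           numeric(1))
  }
  chunk_means <- function(v, nb) {
    edges <- round(seq(0, length(v), length.out = nb + 1))
    vapply(seq_len(nb), function(b) mean(v[(edges[b] + 1):edges[b + 1]]),
           numeric(1))
  }
  c(chunk_means(per_base(gstart - flank, gstart), flank_bins),
    chunk_means(per_base(gstart, gend), body_bins),
    chunk_means(per_base(gend, gend + flank), flank_bins))
}
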