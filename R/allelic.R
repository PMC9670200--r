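## Allele-specific analysis: fragment filtering, SNP-based parental
## assignment (maternal/paternal/unassigned/conflicting, mirroring SNPsplit
## semantics), allelic coverage tracks, per-bin allelic bias, and paired
## region-level comparisons. Sign convention throughout: positive log2
## ratios are maternal-high.

#' Filter fragments by length, MAPQ and duplicate status
#'
#' Retains fragments with length at least `min_len` (140 bp default), MAPQ
#' at least `min_mapq` (30 default) and, by default, no duplicate flag. The
#' number removed by each rule (applied in that order) is attached as
#' attribute `removed`.
#'
#' @param fragments Fragment data frame (see [read_fragments()]).
#' @param min_len Minimum fragment length in bp.
#' @param min_mapq Minimum mapping quality.
#' @param drop_duplicates Drop duplicate-flagged fragments.
#' @return The surviving fragments, with attribute `removed` (named counts).
#' @export
filter_fragments <- function(fragments, min_len = 140, min_mapq = 30,
                             drop_duplicates = TRUE) {
  len_ok <- (fragments$end - fragments$start) >= min_len
  mapq_ok <- fragments$mapq >= min_mapq
  dup_ok <- if (drop_duplicates) !fragments$duplicate else TRUE
  removed <- c(short = sum(!len_ok),
               low_mapq = sum(len_ok & !mapq_ok),
               duplicate = sum(len_ok & mapq_ok & !dup_ok))
  out <- fragments[len_ok & mapq_ok & dup_ok, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Assign parental alleles from SNP evidence
#'
#' For each fragment, counts overlapped SNPs whose observed base matches the
#' maternal vs the paternal base. Maternal-only evidence gives `maternal`,
#' paternal-only `paternal`, none `unassigned`, both `conflicting`. Observed
#' bases matching neither parental base are ignored as sequencing errors.
#'
#' @param fragments Fragment data frame with `snp_calls` list-column.
#' @param snps SNP table (see [read_snp_table()]).
#' @return Data frame with `id`, `allele`, `n_maternal_evidence`,
#'   `n_paternal_evidence`, one row per fragment.
#' @export
assign_alleles <- function(fragments, snps) {
  key <- paste(snps$chrom, snps$pos)
  out <- data.frame(id = fragments$id,
                    allele = character(nrow(fragments)),
                    n_maternal_evidence = integer(nrow(fragments)),
                    n_paternal_evidence = integer(nrow(fragments)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fragments))) {
    sc <- fragments$snp_calls[[i]]
    m <- p <- 0L
    if (nrow(sc)) {
      idx <- match(paste(fragments$chrom[i], sc$pos), key)
      known <- !is.na(idx)
      m <- sum(sc$base[known] == snps$maternal_base[idx[known]])
      p <- sum(sc$base[known] == snps$paternal_base[idx[known]])
    }
    out$allele[i] <- if (m > 0 && p == 0) "maternal"
      else if (p > 0 && m == 0) "paternal"
      else if (m == 0 && p == 0) "unassigned"
      else "conflicting"
    out$n_maternal_evidence[i] <- m
    out$n_paternal_evidence[i] <- p
  }
  out
}

#' Build a coverage track from fragments
#'
#' Counts fragments overlapping each bin and normalizes FPKM-style:
#' `count / (bin_kb * total_fragments_in_millions)`. Used to build allelic
#' tracks from assigned fragments on the same bin grid as combined tracks.
#'
#' @param fragments Fragment data frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param total_fragments Library size used for normalization (defaults to
#'   `nrow(fragments)`; pass the pre-split total so allelic tracks share one
#'   scale).
#' @param allele,stage Metadata labels for the track.
#' @return A [signal_track()].
#' @export
fragments_to_track <- function(fragments, chrom_lengths, bin_size = 1000,
                               total_fragments = nrow(fragments),
                               allele = "both", stage = NA_character_) {
  values <- lapply(names(chrom_lengths), function(chrom) {
    nb <- ceiling(chrom_lengths[[chrom]] / bin_size)
    v <- numeric(nb)
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      b0 <- fr$start[i] %/% bin_size
      b1 <- min((fr$end[i] - 1) %/% bin_size, nb - 1L)
      v[(b0 + 1):(b1 + 1)] <- v[(b0 + 1):(b1 + 1)] + 1
    }
    v
  })
  names(values) <- names(chrom_lengths)
  denom <- (bin_size / 1000) * max(total_fragments, 1) / 1e6
  values <- lapply(values, function(v) v / denom)
  signal_track(values, bin_size, chrom_lengths = chrom_lengths,
               stage = stage, allele = allele)
}

#' Per-bin allelic bias
#'
#' log2((M + pseudocount) / (P + pseudocount)) over all bins where
#' M + P > 0. Positive values are maternal-high.
#'
#' @param track_m,track_p Maternal and paternal [signal_track()]s on the
#'   same genome.
#' @param bin Bias bin size in bp (default 1 kb).
#' @param pseudocount Added to both alleles (default 0.5).
#' @return List with `ratios` (per-bin log2 ratios) and `summary`
#'   (median and quartiles).
#' @export
allelic_bias <- function(track_m, track_p, bin = 1000, pseudocount = 0.5) {
  xy <- track_pair_bins(track_m, track_p, bin)
  xy <- xy[xy[, 1] + xy[, 2] > 0, , drop = FALSE]
  ratios <- log2((xy[, 1] + pseudocount) / (xy[, 2] + pseudocount))
  list(ratios = ratios,
       summary = c(q1 = unname(quantile(ratios, 0.25)),
                   median = median(ratios),
                   q3 = unname(quantile(ratios, 0.75))))
}

#' Compare allelic signal over a region set
#'
#' Computes the mean maternal and paternal signal per region and a paired
#' t-test on the per-region differences (maternal minus paternal). When the
#' differences have zero variance the analytic limit is reported (t = 0 and
#' one-sided p = 0.5 for identical signals) with `degenerate = TRUE`.
#'
#' @param track_m,track_p Maternal and paternal [signal_track()]s.
#' @param regions Region data frame (`chrom`, `start`, `end`), at least 2
#'   rows.
#' @param alternative `"greater"` (maternal higher), `"less"` or
#'   `"two.sided"`.
#' @param paired Paired t-test across matched regions (default) or Welch
#'   unpaired.
#' @return List with `regions` (per-region means and differences),
#'   `t`, `df`, `p_value`, `alternative`, `degenerate`.
#' @export
compare_allelic_regions <- function(track_m, track_p, regions,
                                    alternative = c("greater", "less",
                                                    "two.sided"),
                                    paired = TRUE) {
  alternative <- match.arg(alternative)
  if (nrow(regions) < 2) stop("need at least 2 regions")
  m <- vapply(seq_len(nrow(regions)), function(i)
    track_region_mean(track_m, regions$chrom[i], regions$start[i],
                      regions$end[i]), numeric(1))
  p <- vapply(seq_len(nrow(regions)), function(i)
    track_region_mean(track_p, regions$chrom[i], regions$start[i],
                      regions$end[i]), numeric(1))
  if (paired) {
    d <- m - p
    n <- length(d)
    s <- sd(d)
    df <- n - 1
    if (s == 0) {
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      degenerate <- TRUE
    } else {
      t_stat <- mean(d) / (s / sqrt(n))
      degenerate <- FALSE
    }
  } else {
    vm <- var(m) / length(m)
    vp <- var(p) / length(p)
    if (vm + vp == 0) {
      t_stat <- if (mean(m) == mean(p)) 0 else sign(mean(m) - mean(p)) * Inf
      df <- length(m) - 1
      degenerate <- TRUE
    } else {
      t_stat <- (mean(m) - mean(p)) / sqrt(vm + vp)
      df <- (vm + vp)^2 / (vm^2 / (length(m) - 1) + vp^2 / (length(p) - 1))
      degenerate <- FALSE
    }
  }
  p_greater <- pt(t_stat, df, lower.tail = FALSE)
  p_value <- switch(alternative,
                    greater = p_greater,
                    less = 1 - p_greater,
                    two.sided = 2 * min(p_greater, 1 - p_greater))
  list(regions = data.frame(chrom = regions$chrom, start = regions$start,
                            end = regions$end, maternal = m, paternal = p,
                            difference = m - p, stringsAsFactors = FALSE),
       t = t_stat, df = df, p_value = p_value, alternative = alternative,
       degenerate = degenerate)
}
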