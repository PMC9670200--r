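## Threshold-and-merge acetylation-domain calling. The genome is split into
## fixed-width bins (1 kb for the broad oocyte/zygote regimes, 500 bp for
## the narrow 2-cell/morula/ESC regimes), bins with scaled FPKM at or above
## the threshold become seed domains, and seed domains within twice the bin
## size of each other (end to end, inclusive) are merged.

#' Call acetylation domains on a signal track
#'
#' @param track A [signal_track()] (scaled FPKM); its bin size must divide
#'   `bin_size`, and values are averaged up to `bin_size` before
#'   thresholding.
#' @param bin_size Calling bin width in bp (1000 for broad stages, 500 for
#'   narrow stages).
#' @param threshold Minimum mean FPKM for a qualifying bin (default 3).
#' @param merge_gap Maximum end-to-end gap (bp, inclusive) across which seed
#'   domains are merged; default `2 * bin_size`.
#' @param stage,allele Provenance labels stored on the result (default taken
#'   from the track).
#' @return Data frame of domains: `chrom`, `start`, `end`, `stage`,
#'   `allele`, `mean_signal` (mean over the merged interval, including any
#'   sub-threshold gap bins), sorted and non-overlapping.
#' @export
call_domains <- function(track, bin_size = 1000, threshold = 3,
                         merge_gap = 2 * bin_size,
                         stage = track$stage, allele = track$allele) {
  if (threshold < 0) stop("threshold must be nonnegative")
  if (merge_gap < 0) stop("merge_gap must be nonnegative")
  coarse <- rebin_track(track, bin_size)
  rows <- lapply(track_chroms(coarse), function(chrom) {
    v <- coarse$values[[chrom]]
    runs <- seed_runs(v >= threshold)
    if (!nrow(runs)) return(NULL)
    merged <- merge_runs(runs, gap_bins = merge_gap / bin_size)
    data.frame(
      chrom = chrom,
      start = (merged$first - 1) * bin_size,
      end = pmin(merged$last * bin_size, coarse$chrom_lengths[[chrom]]),
      mean_signal = vapply(seq_len(nrow(merged)), function(i)
        mean(v[merged$first[i]:merged$last[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_signal = numeric(),
                      stringsAsFactors = FALSE)
  out$stage <- rep(if (is.null(stage)) NA_character_ else stage, nrow(out))
  out$allele <- rep(if (is.null(allele)) NA_character_ else allele, nrow(out))
  out[, c("chrom", "start", "end", "stage", "allele", "mean_signal")]
}

## maximal TRUE runs as 1-based first/last bin indices
seed_runs <- function(mask) {
  r <- rle(mask)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(first = first[r$values], last = last[r$values])
}

## merge runs whose gap in bins is <= gap_bins (transitively)
merge_runs <- function(runs, gap_bins) {
  if (nrow(runs) <= 1) return(runs)
  gap <- runs$first[-1] - runs$last[-nrow(runs)] - 1L
  grp <- cumsum(c(1L, as.integer(gap > gap_bins)))
  data.frame(first = as.integer(tapply(runs$first, grp, min)),
             last = as.integer(tapply(runs$last, grp, max)))
}

#' Domain size summary
#'
#' @param domains Domain data frame from [call_domains()].
#' @return Data frame with `n`, `median`, `q1`, `q3`, `total_bases` of the
#'   domain sizes (bp); zero-row input gives a zero-row summary.
#' @export
domain_size_stats <- function(domains) {
  if (!nrow(domains))
    return(data.frame(n = integer(), median = numeric(), q1 = numeric(),
                      q3 = numeric(), total_bases = numeric()))
  sizes <- domains$end - domains$start
  data.frame(n = length(sizes), median = median(sizes),
             q1 = unname(quantile(sizes, 0.25)),
             q3 = unname(quantile(sizes, 0.75)),
             total_bases = sum(sizes))
}

#' Genomic composition of domain bases
#'
#' Partitions every domain base into promoter, exon, intron or intergenic
#' with precedence promoter > exon > intron > intergenic, and returns the
#' fraction of domain bases in each class (summing to 1).
#'
#' @param domains Domain data frame (`chrom`, `start`, `end`).
#' @param genes Gene table with `chrom`, `tss`, exon list-columns
#'   `exon_starts`/`exon_ends`, and `start`/`end` for the gene body.
#' @param promoter_flank Promoter half-width around the TSS in bp.
#' @return Named numeric vector with `promoter`, `exon`, `intron`,
#'   `intergenic` fractions (all 0 for empty input).
#' @export
annotate_domain_bases <- function(domains, genes, promoter_flank = 2000) {
  counts <- c(promoter = 0, exon = 0, intron = 0, intergenic = 0)
  if (!nrow(domains)) return(counts)
  for (chrom in unique(domains$chrom)) {
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    dr <- IRanges::IRanges(start = d$start + 1, end = d$end)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    prom <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1, g$tss - promoter_flank + 1), end = g$tss + promoter_flank))
    exon <- IRanges::reduce(IRanges::IRanges(
      start = unlist(g$exon_starts) + 1, end = unlist(g$exon_ends)))
    body <- IRanges::reduce(IRanges::IRanges(start = g$start + 1, end = g$end))
    total <- sum(IRanges::width(dr))
    in_prom <- overlap_bases(dr, prom)
    exon_np <- IRanges::setdiff(exon, prom)
    in_exon <- overlap_bases(dr, exon_np)
    intron_np <- IRanges::setdiff(IRanges::setdiff(body, exon), prom)
    in_intron <- overlap_bases(dr, intron_np)
    counts["promoter"] <- counts["promoter"] + in_prom
    counts["exon"] <- counts["exon"] + in_exon
    counts["intron"] <- counts["intron"] + in_intron
    counts["intergenic"] <- counts["intergenic"] +
      (total - in_prom - in_exon - in_intron)
  }
  counts / sum(counts)
}

overlap_bases <- function(a, b) {
  sum(IRanges::width(IRanges::intersect(a, b)))
}
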