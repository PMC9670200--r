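## Cross-stage scaling anchored on highly acetylated promoters. Broad and
## narrow signal regimes make raw FPKM incomparable between stages; the top
## promoters are assumed to be near saturation in every stage, so the ratio
## of their median signals (reference over stage) is used as a per-stage
## multiplicative scale factor, with the ESC track as reference (factor 1).

#' Per-gene promoter signal
#'
#' Mean track signal over the promoter window `[TSS - flank, TSS + flank)`,
#' clipped to chromosome bounds (the mean is taken over the available bases
#' only).
#'
#' @param track A [signal_track()].
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @param flank Half-width of the promoter window in bp (default 2 kb).
#' @return Named numeric vector of promoter signals, one per gene.
#' @export
promoter_signal <- function(track, genes, flank = 2000) {
  if (flank <= 0) stop("flank must be positive")
  unknown <- setdiff(unique(genes$chrom), track_chroms(track))
  if (length(unknown))
    stop("gene(s) on chromosome(s) absent from track: ",
         paste(unknown, collapse = ", "))
  out <- vapply(seq_len(nrow(genes)), function(i) {
    track_region_mean(track, genes$chrom[i], genes$tss[i] - flank,
                      genes$tss[i] + flank)
  }, numeric(1))
  setNames(out, genes$gene_id)
}

#' Compute a cross-stage scale factor
#'
#' Ranks promoters by signal independently in the stage and reference
#' tracks, then returns
#' `median(top-n reference promoter signals) / median(top-n stage promoter
#' signals)`. A track identical to the reference therefore has factor 1, and
#' multiplying every stage by its factor equalizes top-promoter medians with
#' the reference. Ties in the ranking are broken by gene id.
#'
#' @param stage_track,reference_track [signal_track()]s on the same genome.
#' @param genes Gene table (see [promoter_signal()]).
#' @param top_n Number of top promoters (default 3000); if fewer genes are
#'   available, all are used with a warning.
#' @param flank Promoter half-width in bp.
#' @return Positive scale factor for the stage.
#' @export
compute_scale_factor <- function(stage_track, reference_track, genes,
                                 top_n = 3000, flank = 2000) {
  if (top_n < 1) stop("top_n must be positive")
  if (nrow(genes) < top_n) {
    warning("only ", nrow(genes), " genes available; using all of them")
    top_n <- nrow(genes)
  }
  top_median <- function(track) {
    sig <- promoter_signal(track, genes, flank)
    ord <- order(-sig, names(sig))
    median(sig[ord[seq_len(top_n)]])
  }
  ref_med <- top_median(reference_track)
  stage_med <- top_median(stage_track)
  if (stage_med == 0)
    stop("degenerate stage track: top-promoter median signal is 0")
  ref_med / stage_med
}

#' Apply a scale factor to a track
#'
#' Multiplies every bin by `factor`; the applied factor is recorded in the
#' track metadata (multiplicatively, so repeated scaling composes).
#'
#' @param track A [signal_track()].
#' @param factor Positive scale factor.
#' @return The scaled `SignalTrack`.
#' @export
apply_scale <- function(track, factor) {
  if (length(factor) != 1 || !is.finite(factor) || factor <= 0)
    stop("factor must be a single positive number")
  track$values <- lapply(track$values, function(v) v * factor)
  track$scale_factor <- track$scale_factor * factor
  track
}

#' Scale-factor table for a set of stage tracks
#'
#' @param tracks Named list of [signal_track()]s (names are stages).
#' @param reference Name of the reference stage (default `"ESC"`).
#' @param genes,top_n,flank Passed to [compute_scale_factor()].
#' @return Data frame with `stage` and `scale_factor`; the reference stage
#'   has factor exactly 1.
#' @export
scale_factor_table <- function(tracks, genes, reference = "ESC",
                               top_n = 3000, flank = 2000) {
  if (!reference %in% names(tracks))
    stop("reference stage '", reference, "' not among tracks")
  factors <- vapply(names(tracks), function(stage) {
    if (stage == reference) 1
    else compute_scale_factor(tracks[[stage]], tracks[[reference]], genes,
                              top_n = top_n, flank = flank)
  }, numeric(1))
  data.frame(stage = names(tracks), scale_factor = unname(factors),
             stringsAsFactors = FALSE)
}
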