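## SignalTrack: stage- and allele-labelled binned coverage over a genome.
## Coordinates are 0-based half-open throughout; bin i covers
## [i*bin_size, (i+1)*bin_size).

#' Create a binned signal track
#'
#' A `SignalTrack` stores nonnegative FPKM-like coverage in fixed-width bins
#' per chromosome. Bin `i` of a chromosome covers base interval
#' `[i*bin_size, (i+1)*bin_size)` (0-based, half-open).
#'
#' @param values Named list, one numeric vector of bin values per chromosome.
#' @param bin_size Bin width in bp (positive integer).
#' @param chrom_lengths Optional named integer vector of chromosome lengths in
#'   bp; defaults to `nbins * bin_size` per chromosome.
#' @param stage Optional stage label (e.g. `"GV"`, `"zygote"`).
#' @param allele One of `"both"`, `"maternal"`, `"paternal"`.
#' @param scale_factor Scale factor already applied to the values (1 = raw).
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(values, bin_size, chrom_lengths = NULL,
                         stage = NA_character_, allele = "both",
                         scale_factor = 1) {
  stopifnot(is.list(values), length(bin_size) == 1L, bin_size >= 1)
  if (is.null(names(values)) && length(values) > 0L)
    stop("'values' must be a named list (names are chromosomes)")
  allele <- match.arg(allele, c("both", "maternal", "paternal"))
  values <- lapply(values, as.numeric)
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (anyNA(v) || any(v < 0))
      stop("negative or missing signal on ", chrom)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(values, function(v) length(v) * bin_size, numeric(1))
  } else {
    chrom_lengths <- chrom_lengths[names(values)]
    bad <- vapply(names(values), function(chrom) {
      length(values[[chrom]]) != ceiling(chrom_lengths[[chrom]] / bin_size)
    }, logical(1))
    if (any(bad))
      stop("bin count inconsistent with chrom_lengths on ",
           paste(names(values)[bad], collapse = ", "))
  }
  ord <- natural_chrom_order(names(values))
  structure(
    list(values = values[ord], bin_size = as.integer(bin_size),
         chrom_lengths = chrom_lengths[names(values)[ord]],
         stage = stage, allele = allele, scale_factor = scale_factor),
    class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d chromosome(s), bin %d bp%s%s\n",
              length(x$values), x$bin_size,
              if (is.na(x$stage)) "" else paste0(", stage ", x$stage),
              if (x$allele == "both") "" else paste0(", ", x$allele, " allele")))
  for (chrom in names(x$values))
    cat(sprintf("  %s: %d bins (%g bp), mean %.3f\n", chrom,
                length(x$values[[chrom]]), x$chrom_lengths[[chrom]],
                mean(x$values[[chrom]])))
  invisible(x)
}

#' Natural chromosome ordering
#'
#' Orders chromosome names so that numeric suffixes sort numerically
#' (chr1 < chr2 < chr10); non-numeric names (chrX, chrM) follow numeric ones
#' lexically.
#'
#' @param chroms Character vector of chromosome names.
#' @return Integer permutation ordering `chroms`.
#' @export
natural_chrom_order <- function(chroms) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chroms)))
  order(is.na(num), num, chroms)
}

track_chroms <- function(track) names(track$values)

n_bins <- function(track, chrom) length(track$values[[chrom]])

## per-base value lookup (0-based positions, vectorized)
track_value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  idx <- pos %/% track$bin_size + 1L
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Mean signal over an interval
#'
#' Per-base mean of the track over `[start, end)`, clipped to chromosome
#' bounds. Partial bin overlaps are length-weighted.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Mean per-base signal (0 if the clipped interval is empty).
#' @export
track_region_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  bs <- track$bin_size
  start <- max(0, start)
  end <- min(track$chrom_lengths[[chrom]], end)
  if (end <= start) return(0)
  b0 <- start %/% bs
  b1 <- (end - 1L) %/% bs
  bins <- b0:b1
  lo <- pmax(bins * bs, start)
  hi <- pmin((bins + 1L) * bs, end)
  sum(v[bins + 1L] * (hi - lo)) / (end - start)
}

#' Re-bin a track to a coarser resolution
#'
#' Aggregates bin values to a larger bin size by the mean, mirroring
#' average-over-bin summaries of coverage tracks.
#'
#' @param track A [signal_track()].
#' @param new_bin_size Target bin width; must be a multiple of the current one.
#' @return A new `SignalTrack` at `new_bin_size`.
#' @export
rebin_track <- function(track, new_bin_size) {
  if (new_bin_size == track$bin_size) return(track)
  if (new_bin_size %% track$bin_size != 0)
    stop("new_bin_size must be a multiple of the track bin size")
  k <- new_bin_size %/% track$bin_size
  values <- lapply(track$values, function(v) {
    nb <- ceiling(length(v) / k)
    grp <- rep(seq_len(nb), each = k, length.out = length(v))
    as.numeric(tapply(v, grp, mean))
  })
  signal_track(values, new_bin_size, chrom_lengths = track$chrom_lengths,
               stage = track$stage, allele = track$allele,
               scale_factor = track$scale_factor)
}

## flatten two tracks on a shared grid into a 2-column matrix of bin values
track_pair_bins <- function(a, b, bin_size) {
  if (!identical(names(a$values), names(b$values)))
    stop("tracks are on different genomes")
  a <- rebin_track(a, bin_size)
  b <- rebin_track(b, bin_size)
  cbind(unlist(a$values, use.names = FALSE),
        unlist(b$values, use.names = FALSE))
}
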