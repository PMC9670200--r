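## Aggregate (pile-up) Hi-C contact analysis between distal-element and
## promoter anchors, normalized by distance-preserving shifted controls: for
## each real anchor pair, control pairs with exactly the same bin separation
## are placed uniformly along the chromosome, and the pile-up reports the
## elementwise observed/control ratio of the mean submatrices.

#' Enumerate candidate anchor pairs
#'
#' Cartesian product of peaks and promoter regions restricted to
#' same-chromosome pairs whose bin separation (at `resolution`, using
#' interval midpoints) lies in `[min_sep, max_sep]`, deduplicated at bin
#' resolution.
#'
#' @param peaks Data frame (`chrom`, `start`, `end`) of distal elements.
#' @param promoters Data frame (`chrom`, `start`, `end`) of promoter
#'   regions.
#' @param resolution Bin width in bp.
#' @param min_sep Minimum bin separation (default 2 bins).
#' @param max_sep Maximum bin separation (default unlimited).
#' @return Data frame of anchor pairs: `chrom`, `bin_a`, `bin_b` (with
#'   `bin_a <= bin_b`).
#' @export
enumerate_anchor_pairs <- function(peaks, promoters, resolution = 10000,
                                   min_sep = 2, max_sep = Inf) {
  if (!nrow(peaks) || !nrow(promoters)) stop("empty anchor set")
  bin_of <- function(df) floor((df$start + df$end) / 2) %/% resolution
  pk <- data.frame(chrom = peaks$chrom, bin = bin_of(peaks))
  pr <- data.frame(chrom = promoters$chrom, bin = bin_of(promoters))
  pairs <- merge(pk, pr, by = "chrom", suffixes = c("_a", "_b"))
  sep <- abs(pairs$bin_a - pairs$bin_b)
  pairs <- pairs[sep >= min_sep & sep <= max_sep, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(chrom = character(), bin_a = integer(),
                      bin_b = integer(), stringsAsFactors = FALSE))
  out <- data.frame(chrom = pairs$chrom,
                    bin_a = pmin(pairs$bin_a, pairs$bin_b),
                    bin_b = pmax(pairs$bin_a, pairs$bin_b),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$chrom, out$bin_a, out$bin_b), , drop = FALSE]
}

#' Pile-up of Hi-C contacts at anchor pairs
#'
#' `observed` is the elementwise mean over anchor pairs of the
#' `(2w+1) x (2w+1)` contact submatrix centered on each pair; `control` is
#' the same mean over `nshifts` randomized pairs per real pair, shifted
#' along the chromosome with the bin separation preserved exactly. The
#' control placement for each pair is seeded from the pair's own
#' coordinates, so the result is independent of pair order. Pairs whose
#' window leaves the matrix are dropped and counted.
#'
#' @param contacts A `ContactMatrix` (see [read_contacts()]).
#' @param pairs Anchor pairs from [enumerate_anchor_pairs()].
#' @param w Window half-width in bins (default 5, i.e. +-50 kb at 10 kb).
#' @param nshifts Shifted control pairs per real pair (default 1).
#' @param seed Integer seed for control placement (default 0).
#' @param keep_controls Also return the control pair coordinates (for
#'   auditing the distance-preservation guarantee).
#' @return Object of class `pileup_result`: list with `ratio` (the
#'   `(2w+1) x (2w+1)` observed/control matrix, `NA` where the control is
#'   0), `observed`, `control`, `center_ratio`, `n_pairs` used and
#'   `n_dropped` (plus `control_pairs` when `keep_controls`).
#' @export
pileup <- function(contacts, pairs, w = 5, nshifts = 1, seed = 0,
                   keep_controls = FALSE) {
  if (!nrow(pairs)) stop("no anchor pairs")
  missing_chrom <- setdiff(unique(pairs$chrom), names(contacts$matrices))
  if (length(missing_chrom))
    stop("pairs on chromosome(s) absent from contacts: ",
         paste(missing_chrom, collapse = ", "))
  size <- 2 * w + 1
  obs_acc <- matrix(0, size, size)
  ctl_acc <- matrix(0, size, size)
  n_used <- 0L
  n_ctl <- 0L
  n_dropped <- 0L
  chrom_index <- setNames(seq_along(contacts$matrices),
                          names(contacts$matrices))
  control_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    m <- contacts$matrices[[pairs$chrom[i]]]
    nb <- nrow(m)
    a <- pairs$bin_a[i]
    b <- pairs$bin_b[i]
    if (a - w < 0 || b - w < 0 || a + w >= nb || b + w >= nb) {
      n_dropped <- n_dropped + 1L
      next
    }
    obs_acc <- obs_acc + m[(a - w):(a + w) + 1L, (b - w):(b + w) + 1L]
    n_used <- n_used + 1L
    sep <- b - a
    pair_seed <- (abs(seed) %% 65011 * 2654435761 +
                  a * 40503 + b * 69069 +
                  chrom_index[[pairs$chrom[i]]] * 8191) %% 2147480009
    ctl <- with_seed(as.integer(pair_seed), {
      lapply(seq_len(nshifts), function(s) {
        ca <- sample.int(nb - sep - 2 * w, 1) + w - 1L  # 0-based, window fits
        c(ca, ca + sep)
      })
    })
    for (cp in ctl) {
      ctl_acc <- ctl_acc +
        m[(cp[1] - w):(cp[1] + w) + 1L, (cp[2] - w):(cp[2] + w) + 1L]
      n_ctl <- n_ctl + 1L
      if (keep_controls)
        control_rows[[length(control_rows) + 1L]] <- data.frame(
          chrom = pairs$chrom[i], real_a = a, real_b = b,
          bin_a = cp[1], bin_b = cp[2], stringsAsFactors = FALSE)
    }
  }
  if (n_used == 0) stop("all anchor pairs dropped (windows out of bounds)")
  observed <- obs_acc / n_used
  control <- ctl_acc / n_ctl
  ratio <- observed / control
  ratio[control == 0] <- NA_real_
  out <- list(ratio = ratio, observed = observed, control = control,
              center_ratio = ratio[w + 1, w + 1], w = w,
              n_pairs = n_used, n_dropped = n_dropped,
              n_masked = sum(control == 0))
  if (keep_controls) out$control_pairs <- do.call(rbind, control_rows)
  structure(out, class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat(sprintf(paste0("Hi-C pile-up: %d pair(s) used, %d dropped; ",
                     "center observed/control ratio %.3f\n"),
              x$n_pairs, x$n_dropped, x$center_ratio))
  invisible(x)
}
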