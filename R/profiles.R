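## Stage-to-stage dynamics: domain-transition clustering, track
## correlations, metagene/TSS enrichment profiles, gene-density correlation,
## and peak classification by TSS distance and perturbation response.

#' Build a domain-by-position signal matrix
#'
#' One row per domain; columns are `nbins` positional bins spanning a fixed
#' flank around the domain center, one block ("layer") per track, layers
#' concatenated in the order given. Used as the feature matrix for
#' domain-transition clustering.
#'
#' @param domains Domain data frame (`chrom`, `start`, `end`).
#' @param tracks Named list of [signal_track()]s (stages/marks).
#' @param flank Half-window around the domain center in bp.
#' @param nbins Positional bins per layer.
#' @return Numeric matrix with `nrow(domains)` rows and
#'   `nbins * length(tracks)` columns; attribute `layers` gives the track
#'   names.
#' @export
domain_signal_matrix <- function(domains, tracks, flank = 10000, nbins = 100) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  mat <- matrix(0, nrow(domains), nbins * length(tracks))
  centers <- floor((domains$start + domains$end) / 2)
  edges <- seq(-flank, flank, length.out = nbins + 1)
  for (li in seq_along(tracks)) {
    track <- tracks[[li]]
    for (i in seq_len(nrow(domains))) {
      mat[i, (li - 1) * nbins + seq_len(nbins)] <-
        vapply(seq_len(nbins), function(b)
          track_region_mean(track, domains$chrom[i],
                            centers[i] + edges[b], centers[i] + edges[b + 1]),
          numeric(1))
    }
  }
  attr(mat, "layers") <- names(tracks)
  attr(mat, "nbins") <- nbins
  mat
}

#' Cluster domain transitions by k-means
#'
#' K-means with a fixed seed and `nstart` restarts. For determinism the rows
#' are clustered in a canonical (lexicographic) order, so the result is
#' invariant to the input row order, and cluster labels are reassigned in
#' descending order of the cluster mean over the first layer (label 1 =
#' highest first-layer signal). Degenerate inputs with fewer distinct rows
#' than `k` collapse onto the distinct rows (duplicate centroids), without
#' error.
#'
#' @param mat Feature matrix from [domain_signal_matrix()] (or any numeric
#'   matrix with at least `k` rows).
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (best objective kept).
#' @return List with `labels` (integer per row), `centers`, `withinss`,
#'   `tot_withinss`, and `profiles` (per-cluster mean rows).
#' @export
cluster_domain_transitions <- function(mat, k = 3, seed = 0, nstart = 10) {
  mat <- as.matrix(mat)
  if (k < 2) stop("k must be at least 2")
  if (nrow(mat) < k) stop("fewer rows than clusters")
  ord <- do.call(order, as.data.frame(mat))
  m <- mat[ord, , drop = FALSE]
  n_unique <- nrow(unique(m))
  k_eff <- min(k, n_unique)
  fit <- with_seed(substream_seed(seed, "kmeans"), {
    if (k_eff < 2) {
      list(cluster = rep(1L, nrow(m)),
           centers = matrix(m[1, ], 1, ncol(m)),
           withinss = sum(sweep(m, 2, m[1, ])^2),
           tot.withinss = sum(sweep(m, 2, m[1, ])^2))
    } else kmeans(m, centers = k_eff, nstart = nstart, iter.max = 100)
  })
  labels <- integer(nrow(mat))
  labels[ord] <- fit$cluster
  centers <- fit$centers
  if (k_eff < k) {  # pad with duplicate centroids so k clusters are reported
    centers <- centers[c(seq_len(k_eff), rep(k_eff, k - k_eff)), , drop = FALSE]
  }
  nbins <- attr(mat, "nbins")
  first_layer <- seq_len(if (is.null(nbins)) ncol(mat) else nbins)
  relabel <- order(-rowMeans(centers[, first_layer, drop = FALSE]))
  new_of_old <- match(seq_len(k), relabel)
  labels <- new_of_old[labels]
  centers <- centers[relabel, , drop = FALSE]
  withinss <- rep(0, k)
  withinss[new_of_old[seq_along(fit$withinss)]] <- fit$withinss
  profiles <- do.call(rbind, lapply(seq_len(k), function(cl) {
    rows <- mat[labels == cl, , drop = FALSE]
    if (nrow(rows)) colMeans(rows) else rep(NA_real_, ncol(mat))
  }))
  list(labels = labels, centers = centers, withinss = withinss,
       tot_withinss = fit$tot.withinss, profiles = profiles)
}

#' Genome-wide correlation between two tracks
#'
#' Tracks are re-binned to `bin` (default 5 kb) and correlated over all
#' bins; bins where both tracks are exactly 0 are excluded by default
#' (sparse embryo tracks are otherwise dominated by double-zero ties).
#'
#' @param track_a,track_b [signal_track()]s on the same genome.
#' @param bin Correlation bin size in bp.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param drop_double_zero Exclude bins that are 0 in both tracks.
#' @return Correlation coefficient.
#' @export
correlate_tracks <- function(track_a, track_b, bin = 5000,
                             method = c("spearman", "pearson"),
                             drop_double_zero = TRUE) {
  method <- match.arg(method)
  xy <- track_pair_bins(track_a, track_b, bin)
  if (drop_double_zero) xy <- xy[xy[, 1] != 0 | xy[, 2] != 0, , drop = FALSE]
  if (nrow(xy) < 3) stop("fewer than 3 bins retained for correlation")
  cor(xy[, 1], xy[, 2], method = method)
}

#' Correlation between gene density and signal
#'
#' Spearman correlation between the per-window TSS count and the mean track
#' signal over non-overlapping windows.
#'
#' @param track A [signal_track()].
#' @param genes Gene table with `chrom`, `tss`.
#' @param window Window size in bp (default 100 kb); must be at least the
#'   track bin size.
#' @return Spearman correlation.
#' @export
gene_density_correlation <- function(track, genes, window = 1e5) {
  if (window < track$bin_size) stop("window smaller than track bin")
  counts <- numeric(0)
  signal <- numeric(0)
  for (chrom in track_chroms(track)) {
    len <- track$chrom_lengths[[chrom]]
    nw <- ceiling(len / window)
    tss <- genes$tss[genes$chrom == chrom]
    counts <- c(counts, tabulate(pmin(tss %/% window + 1L, nw), nbins = nw))
    signal <- c(signal, vapply(seq_len(nw) - 1L, function(wi)
      track_region_mean(track, chrom, wi * window, (wi + 1) * window),
      numeric(1)))
  }
  if (sd(counts) == 0 || sd(signal) == 0)
    stop("correlation undefined: constant gene density or signal")
  cor(counts, signal, method = "spearman")
}

#' Metagene enrichment profile
#'
#' Upstream flank, gene body rescaled to a fixed number of bins, and
#' downstream flank, averaged across genes. Minus-strand genes are reversed
#' so the profile always reads TSS to TES left to right. Genes whose body is
#' shorter than `body_bins` bases are skipped and counted.
#'
#' @param track A [signal_track()].
#' @param genes Gene table with `chrom`, `strand`, `tss`, `tes`.
#' @param body_bins Bins across the gene body.
#' @param flank Flank length in bp on each side.
#' @param flank_bins Bins across each flank.
#' @return Object of class `MetaProfile`: list with `profile` (mean signal
#'   per positional bin), `n_genes` used, `n_skipped`, and the bin layout.
#' @export
metagene_profile <- function(track, genes, body_bins = 60, flank = 2000,
                             flank_bins = 20) {
  if (!nrow(genes)) stop("empty gene list")
  total_bins <- 2 * flank_bins + body_bins
  acc <- numeric(total_bins)
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    glen <- abs(genes$tes[i] - genes$tss[i])
    if (glen < body_bins) { skipped <- skipped + 1L; next }
    minus <- genes$strand[i] == "-"
    gstart <- min(genes$tss[i], genes$tes[i])
    gend <- max(genes$tss[i], genes$tes[i])
    up <- bin_means(track, genes$chrom[i], gstart - flank, gstart, flank_bins)
    body <- bin_means(track, genes$chrom[i], gstart, gend, body_bins)
    down <- bin_means(track, genes$chrom[i], gend, gend + flank, flank_bins)
    prof <- c(up, body, down)
    if (minus) prof <- rev(prof)
    acc <- acc + prof
    used <- used + 1L
  }
  if (used == 0) stop("no gene long enough for the requested body_bins")
  structure(list(profile = acc / used, n_genes = used, n_skipped = skipped,
                 flank = flank, flank_bins = flank_bins,
                 body_bins = body_bins), class = "MetaProfile")
}

## equal-width positional bin means over [start, end), clipped per bin
bin_means <- function(track, chrom, start, end, nbins) {
  edges <- seq(start, end, length.out = nbins + 1)
  vapply(seq_len(nbins), function(b)
    track_region_mean(track, chrom, floor(edges[b]), ceiling(edges[b + 1])),
    numeric(1))
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile: %d bins over %d gene(s)%s\n", length(x$profile),
              x$n_genes,
              if (x$n_skipped) sprintf(" (%d skipped)", x$n_skipped) else ""))
  invisible(x)
}

#' TSS-centered enrichment profile
#'
#' As [metagene_profile()] but centered on the TSS without body rescaling:
#' the window `[TSS - flank, TSS + flank)` is split into `nbins` bins,
#' strand-aware, and averaged across sites.
#'
#' @param track A [signal_track()].
#' @param tss_list Data frame with `chrom`, `tss` and optionally `strand`.
#' @param flank Half-window in bp (default 2 kb).
#' @param nbins Number of positional bins.
#' @return A `MetaProfile` (with `body_bins = 0`).
#' @export
tss_profile <- function(track, tss_list, flank = 2000, nbins = 40) {
  if (!nrow(tss_list)) stop("empty TSS list")
  acc <- numeric(nbins)
  for (i in seq_len(nrow(tss_list))) {
    prof <- bin_means(track, tss_list$chrom[i], tss_list$tss[i] - flank,
                      tss_list$tss[i] + flank, nbins)
    if (!is.null(tss_list$strand) && tss_list$strand[i] == "-")
      prof <- rev(prof)
    acc <- acc + prof
  }
  structure(list(profile = acc / nrow(tss_list), n_genes = nrow(tss_list),
                 n_skipped = 0L, flank = flank, flank_bins = nbins %/% 2,
                 body_bins = 0L), class = "MetaProfile")
}

#' Classify peaks by distance to the nearest TSS
#'
#' Distance is measured from the peak midpoint to the nearest TSS. Peaks
#' closer than `promoter_dist` (default 1 kb) are promoter peaks, peaks
#' farther than `distal_dist` (default 2.5 kb) are distal peaks, and the
#' remainder are labelled `"other"`.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`).
#' @param tss_list Data frame with `chrom`, `tss`.
#' @param promoter_dist,distal_dist Distance cutoffs in bp.
#' @return Character vector of labels (`"promoter"`, `"distal"`, `"other"`),
#'   one per peak, with the midpoint distances as attribute `distance`.
#' @export
classify_peaks_by_tss <- function(peaks, tss_list, promoter_dist = 1000,
                                  distal_dist = 2500) {
  mid <- floor((peaks$start + peaks$end) / 2)
  dist <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- tss_list$tss[tss_list$chrom == peaks$chrom[i]]
    if (!length(tss)) return(Inf)
    min(abs(tss - mid[i]))
  }, numeric(1))
  labels <- ifelse(dist < promoter_dist, "promoter",
                   ifelse(dist > distal_dist, "distal", "other"))
  attr(labels, "distance") <- dist
  labels
}

#' Classify peak response between two conditions
#'
#' Per-peak mean signal ratio (treated over control, with a pseudocount):
#' at or below `lost_ratio` is `"lost"`, at or above `gain_ratio` is
#' `"enhanced"`, otherwise `"unaffected"`. The ratio thresholds are package
#' defaults, not literature values.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`).
#' @param signal_control,signal_treated [signal_track()]s on the same
#'   genome.
#' @param lost_ratio,gain_ratio Ratio cutoffs (defaults 0.5 and 2).
#' @param pseudocount Added to both means before the ratio.
#' @return Character vector of labels with the ratios as attribute `ratio`.
#' @export
classify_peak_response <- function(peaks, signal_control, signal_treated,
                                   lost_ratio = 0.5, gain_ratio = 2,
                                   pseudocount = 0.5) {
  ratio <- vapply(seq_len(nrow(peaks)), function(i) {
    ctrl <- track_region_mean(signal_control, peaks$chrom[i], peaks$start[i],
                              peaks$end[i])
    trt <- track_region_mean(signal_treated, peaks$chrom[i], peaks$start[i],
                             peaks$end[i])
    (trt + pseudocount) / (ctrl + pseudocount)
  }, numeric(1))
  labels <- ifelse(ratio <= lost_ratio, "lost",
                   ifelse(ratio >= gain_ratio, "enhanced", "unaffected"))
  attr(labels, "ratio") <- ratio
  labels
}
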