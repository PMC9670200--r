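test_that("k-means recovers a planted two-level partition exactly", {
  set.seed(10)
  mat <- rbind(matrix(10 + rnorm(5 * 8, 0, 0.01), 5, 8),
               matrix(0 + abs(rnorm(6 * 8, 0, 0.01)), 6, 8))
  fit <- cluster_domain_transitions(mat, k = 2, seed = 1)
  oracle <- oracle_best_2partition(mat)
  expect_equal(fit$labels, oracle$labels)  # label 1 = high cluster
  expect_equal(fit$tot_withinss, oracle$ss, tolerance = 1e-6)
})

test_that("identical rows collapse without error", {
  mat <- matrix(5, 6, 4)
  fit <- cluster_domain_transitions(mat, k = 2, seed = 1)
  expect_equal(fit$labels, rep(1L, 6))
  expect_equal(nrow(fit$centers), 2)  # duplicate centroids
  expect_error(cluster_domain_transitions(matrix(1, 1, 3), k = 2), "fewer")
})

test_that("clustering is invariant to row order", {
  set.seed(21)
  mat <- rbind(matrix(10, 4, 6), matrix(5, 4, 6), matrix(0, 4, 6)) +
    matrix(rnorm(72, 0, 0.1), 12, 6)
  fit <- cluster_domain_transitions(mat, k = 3, seed = 9)
  perm <- sample(nrow(mat))
  fit_p <- cluster_domain_transitions(mat[perm, ], k = 3, seed = 9)
  expect_equal(fit_p$labels, fit$labels[perm])
})

test_that("domain signal matrices stack per-stage layers around centers", {
  g <- small_genome()
  st <- generate_stage_tracks(g, stage_params("GV", noise_sd = 0), seed = 12)
  dom <- call_domains(st$combined, 1000)
  mat <- domain_signal_matrix(dom, list(GV = st$combined), flank = 5000,
                              nbins = 10)
  expect_equal(dim(mat), c(nrow(dom), 10))
  ## center bins sit inside the plateau
  expect_true(all(mat[, 5:6] == 8))
})

test_that("track correlation behaves on identity, antitone and hand cases", {
  v <- c(1, 4, 2, 8, 5, 7)
  a <- vec_track(v, 5000)
  expect_equal(correlate_tracks(a, a), 1)
  b <- vec_track(max(v) - v, 5000)
  expect_equal(correlate_tracks(a, b), -1)

  w <- c(2, 1, 5, 3, 9, 4)
  expect_equal(correlate_tracks(a, vec_track(w, 5000)),
               oracle_spearman(v, w))
  expect_equal(correlate_tracks(a, vec_track(w, 5000), method = "pearson"),
               cor(v, w))
  ## double-zero bins are dropped before correlating
  a0 <- vec_track(c(v, 0, 0), 5000)
  w0 <- vec_track(c(w, 0, 0), 5000)
  expect_equal(correlate_tracks(a0, w0), oracle_spearman(v, w))
  expect_error(correlate_tracks(vec_track(c(0, 0, 0), 5000),
                                vec_track(c(0, 0, 0), 5000)), "fewer than 3")
})

test_that("gene density correlates with planted signal", {
  g <- small_genome()
  zy <- generate_stage_tracks(g, stage_params("zygote", noise_sd = 0),
                              seed = 5)
  ## TSSs planted every 10 kb inside domains, none outside, background 0:
  ## gene density is then proportional to domain coverage
  truth <- zy$truth[zy$truth$allele == "both", ]
  genes <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    tss <- seq(truth$start[i] + 5000, truth$end[i] - 1, by = 10000)
    data.frame(gene_id = sprintf("g%d_%d", i, seq_along(tss)),
               chrom = truth$chrom[i], tss = tss, stringsAsFactors = FALSE)
  }))
  bg0 <- zy$combined
  bg0$values <- lapply(bg0$values, function(v) ifelse(v < 3, 0, v))
  expect_gt(gene_density_correlation(bg0, genes, window = 1e5), 0.9)

  uni <- uniform_track(2, g$chromosomes, 1000)
  expect_error(gene_density_correlation(uni, genes, window = 1e5),
               "undefined")

  ## doubling the window merges TSS counts consistently with a recount
  nw <- ceiling(g$chromosomes[["chr1"]] / 1e5)
  counts1 <- tabulate(genes$tss[genes$chrom == "chr1"] %/% 1e5 + 1, nw)
  counts2 <- tabulate(genes$tss[genes$chrom == "chr1"] %/% 2e5 + 1, nw / 2)
  expect_equal(colSums(matrix(counts1, nrow = 2)), counts2)
})

test_that("metagene profiles match the per-base rescaling oracle", {
  g_len <- 20000
  tr <- vec_track(c(rep(1, 5), rep(9, 5), rep(2, 10)), 1000,
                  chrom_lengths = c(chr1 = g_len))
  expect_equal(
    metagene_profile(tr, data.frame(gene_id = "u", chrom = "chr1",
                                    strand = "+", tss = 6000, tes = 12000),
                     body_bins = 6, flank = 2000, flank_bins = 2)$profile,
    oracle_gene_profile(tr, "chr1", 6000, 12000, 6, 2000, 2))

  ## uniform track gives a flat profile at the track value
  uni <- vec_track(rep(4, 20), 1000)
  prof <- metagene_profile(uni, data.frame(gene_id = "u", chrom = "chr1",
                                           strand = "+", tss = 5000,
                                           tes = 15000),
                           body_bins = 10, flank = 2000, flank_bins = 4)
  expect_equal(prof$profile, rep(4, 18))

  ## a minus-strand gene mirrors the plus-strand profile
  genes_p <- data.frame(gene_id = "p", chrom = "chr1", strand = "+",
                        tss = 6000, tes = 12000, stringsAsFactors = FALSE)
  genes_m <- data.frame(gene_id = "m", chrom = "chr1", strand = "-",
                        tss = 12000, tes = 6000, stringsAsFactors = FALSE)
  pp <- metagene_profile(tr, genes_p, 6, 2000, 2)$profile
  pm <- metagene_profile(tr, genes_m, 6, 2000, 2)$profile
  expect_equal(pm, rev(pp))

  ## too-short genes are skipped and counted
  mix <- rbind(genes_p, data.frame(gene_id = "tiny", chrom = "chr1",
                                   strand = "+", tss = 100, tes = 103))
  prof2 <- metagene_profile(tr, mix, body_bins = 6, flank = 2000,
                            flank_bins = 2)
  expect_equal(prof2$n_genes, 1)
  expect_equal(prof2$n_skipped, 1)
})

test_that("TSS profiles are strand-aware and flat on uniform tracks", {
  uni <- vec_track(rep(3, 20), 1000)
  sites <- data.frame(chrom = "chr1", tss = 10000, strand = "+")
  expect_equal(tss_profile(uni, sites, flank = 2000, nbins = 8)$profile,
               rep(3, 8))
  step <- vec_track(c(rep(1, 10), rep(7, 10)), 1000)
  fwd <- tss_profile(step, sites, flank = 2000, nbins = 8)$profile
  rev_site <- data.frame(chrom = "chr1", tss = 10000, strand = "-")
  bwd <- tss_profile(step, rev_site, flank = 2000, nbins = 8)$profile
  expect_equal(bwd, rev(fwd))
  expect_equal(fwd, c(rep(1, 4), rep(7, 4)))
})

test_that("peak-TSS classification applies the printed distance cutoffs", {
  tss <- data.frame(chrom = "chr1", tss = 10000)
  peak_at <- function(mid) data.frame(chrom = "chr1", start = mid - 100,
                                      end = mid + 100)
  expect_equal(unclass(classify_peaks_by_tss(peak_at(10500), tss))[1],
               "promoter")   # 500 bp < 1 kb
  expect_equal(unclass(classify_peaks_by_tss(peak_at(13000), tss))[1],
               "distal")     # 3 kb > 2.5 kb
  expect_equal(unclass(classify_peaks_by_tss(peak_at(11500), tss))[1],
               "other")      # between the printed bounds
  ## labels partition the peaks
  set.seed(3)
  peaks <- do.call(rbind, lapply(round(runif(50, 200, 50000)), peak_at))
  labels <- classify_peaks_by_tss(peaks, tss)
  expect_true(all(labels %in% c("promoter", "distal", "other")))
  expect_length(labels, 50)
})

test_that("peak response classes follow the ratio thresholds", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 5000, 10000),
                      end = c(2000, 7000, 12000))
  ctrl <- vec_track(rep(4, 15), 1000)
  same <- classify_peak_response(peaks, ctrl, ctrl)
  expect_true(all(same == "unaffected"))

  treated <- vec_track(c(0, 0, rep(4, 3), 16, 16, rep(4, 8)), 1000)
  labels <- classify_peak_response(peaks, ctrl, treated)
  expect_equal(unclass(labels)[1:3], c("lost", "enhanced", "unaffected"),
               ignore_attr = TRUE)
})
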