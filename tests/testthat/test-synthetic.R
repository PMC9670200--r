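test_that("genome generation is deterministic and honours the config", {
  cfg <- list(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), n_genes = 50,
              with_sequence = FALSE)
  g1 <- generate_genome(cfg, seed = 7)
  g2 <- generate_genome(cfg, seed = 7)
  expect_equal(g1, g2)

  g0 <- generate_genome(list(chrom_lengths = c(chr1 = 1e6), n_genes = 0,
                             with_sequence = FALSE), seed = 1)
  expect_equal(nrow(g0$genes), 0)

  expect_error(generate_genome(list(bogus_key = 1)), "unknown")
})

test_that("gene packing fails loudly when infeasible", {
  expect_error(
    generate_genome(list(chrom_lengths = c(chr1 = 2e5), n_genes = 100,
                         with_sequence = FALSE), seed = 1),
    "infeasible")
})

test_that("SNP counts follow the Poisson expectation", {
  g <- test_genome()  # 10 Mb at 1 kb spacing
  lambda <- sum(g$chromosomes) / g$config$snp_spacing
  expect_lt(abs(nrow(g$snps) - lambda), 3 * sqrt(lambda))
  expect_true(all(g$snps$maternal_base != g$snps$paternal_base))
})

test_that("zero-noise tracks are exact piecewise plateaus", {
  g <- small_genome()
  st <- generate_stage_tracks(g, stage_params("GV", noise_sd = 0), seed = 3)
  tr <- st$combined
  truth <- st$truth[st$truth$allele == "both", ]
  for (chrom in names(tr$values)) {
    v <- tr$values[[chrom]]
    planted <- rep(FALSE, length(v))
    d <- truth[truth$chrom == chrom, ]
    for (i in seq_len(nrow(d)))
      planted[(d$start[i] %/% tr$bin_size + 1):(d$end[i] %/% tr$bin_size)] <- TRUE
    expect_true(all(v[planted] == 8))     # plateau FPKM
    expect_true(all(v[!planted] == 0.5))  # background FPKM
  }
})

test_that("allelic asymmetry scales the paternal plateau and width", {
  g <- small_genome()
  sym <- generate_stage_tracks(g, stage_params("GV"), seed = 3)
  expect_equal(sym$maternal$values, sym$paternal$values)  # asymmetry 1

  zy <- generate_stage_tracks(g, stage_params("zygote", noise_sd = 0),
                              seed = 3)
  tm <- zy$truth[zy$truth$allele == "maternal", ]
  tp <- zy$truth[zy$truth$allele == "paternal", ]
  ## paternal plateau is 2x at every maternal planted bin
  i <- 1
  mid <- floor((tm$start[i] + tm$end[i]) / 2)
  expect_equal(track_value_at(zy$paternal, tm$chrom[i], mid) /
               track_value_at(zy$maternal, tm$chrom[i], mid), 2)
  ## paternal intervals contain and double the maternal ones
  expect_true(all(tp$start <= tm$start & tp$end >= tm$end))
  expect_equal(sum(tp$end - tp$start) / sum(tm$end - tm$start), 2,
               tolerance = 0.05)
  ## combined is the mean of the alleles
  expect_equal(zy$combined$values$chr1,
               (zy$maternal$values$chr1 + zy$paternal$values$chr1) / 2)
})

test_that("fragments carry true-allele SNP evidence and honest flags", {
  g <- test_genome()
  zy <- generate_stage_tracks(g, stage_params("zygote"), seed = 1)
  fr <- generate_allelic_fragments(g, zy$maternal, zy$paternal, 2000,
                                   seed = 1, contaminant_frac = 0,
                                   low_mapq_frac = 0, dup_rate = 0)
  kept <- filter_fragments(fr)
  expect_equal(nrow(kept), 2000)  # all clean fragments pass the filters

  ## every SNP call reports the true allele's base
  snp_key <- paste(g$snps$chrom, g$snps$pos)
  for (i in sample(which(vapply(fr$snp_calls, nrow, 0L) > 0), 50)) {
    sc <- fr$snp_calls[[i]]
    idx <- match(paste(fr$chrom[i], sc$pos), snp_key)
    expected <- if (fr$true_allele[i] == "maternal")
      g$snps$maternal_base[idx] else g$snps$paternal_base[idx]
    expect_equal(sc$base, expected)
  }
  expect_error(generate_allelic_fragments(g, zy$maternal, zy$paternal, 0),
               "positive")
})

test_that("fragment SNP coverage matches the analytic expectation", {
  g <- test_genome()
  zy <- generate_stage_tracks(g, stage_params("zygote"), seed = 2)
  n <- 10000
  fr <- generate_allelic_fragments(g, zy$maternal, zy$paternal, n, seed = 2,
                                   contaminant_frac = 0, low_mapq_frac = 0,
                                   dup_rate = 0)
  frac <- mean(vapply(fr$snp_calls, nrow, 0L) > 0)
  ## P(>=1 SNP) = 1 - E_L[exp(-lambda L)], L ~ U(140, 500)
  lambda <- nrow(g$snps) / sum(g$chromosomes)
  expectation <- 1 - (exp(-lambda * 140) - exp(-lambda * 500)) /
    (lambda * (500 - 140))
  se <- sqrt(expectation * (1 - expectation) / n)
  expect_lt(abs(frac - expectation), 3 * se)
})

test_that("contact backgrounds are flat at alpha 0 and loops lift the mean", {
  g <- small_genome()
  cm <- generate_contact_matrix(g, 50000, seed = 4, alpha = 0,
                                mean_count = 30)
  m <- cm$matrices$chr1
  expect_equal(m, t(m))
  expect_equal(mean(m[upper.tri(m)]), 30, tolerance = 0.05)

  loops <- data.frame(chrom = "chr1", bin_a = c(2, 10), bin_b = c(8, 17),
                      fold = 1)
  cm_f1 <- generate_contact_matrix(g, 50000, loops, seed = 4, alpha = 0,
                                   mean_count = 30)
  expect_equal(cm_f1$matrices, cm$matrices)  # fold-1 loops change nothing

  expect_error(generate_contact_matrix(
    g, 50000, data.frame(chrom = "chr1", bin_a = 1, bin_b = 1e4, fold = 2),
    seed = 1), "outside")
})

test_that("planted loop enrichment matches the Poisson ratio oracle", {
  g <- test_genome()
  loops <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                      bin_a = rep(c(40, 90, 140, 190, 240), 2),
                      bin_b = rep(c(60, 110, 160, 210, 260), 2), fold = 8)
  cm <- generate_contact_matrix(g, 10000, loops, seed = 6, alpha = 0,
                                mean_count = 25)
  at_loops <- mapply(function(chrom, a, b) cm$matrices[[chrom]][a + 1, b + 1],
                     loops$chrom, loops$bin_a, loops$bin_b)
  background <- mean(cm$matrices$chr1[upper.tri(cm$matrices$chr1)])
  expect_gt(mean(at_loops) / background, 6)
  expect_lt(mean(at_loops) / background, 10)
})

test_that("expression tables encode the planted gene classes", {
  g <- test_genome()
  tabs <- generate_expression_tables(g, seed = 5)
  classes <- g$truth$gene_classes

  ## PcG targets silent everywhere, below the 0.1 threshold
  expect_true(all(tabs$expression[classes$pcg_target, ] < 0.1))
  ## null genes appear in no derived set
  sets <- derive_gene_sets(tabs)
  member <- unique(unlist(lapply(sets, `[[`, "gene_ids")))
  null_genes <- setdiff(rownames(tabs$expression), unlist(classes))
  expect_length(intersect(null_genes, member), 0)
  ## end-to-end: every derived set equals its ledger class
  for (nm in names(sets))
    expect_equal(sets[[nm]]$gene_ids, sort(classes[[nm]]))
})

test_that("generators are reproducible and use independent substreams", {
  g <- small_genome()
  a <- generate_stage_tracks(g, stage_params("GV"), seed = 8)
  b <- generate_stage_tracks(g, stage_params("GV"), seed = 8)
  expect_equal(a, b)
  ## drawing fragments does not change track generation
  zy <- generate_stage_tracks(g, stage_params("zygote"), seed = 8)
  invisible(generate_allelic_fragments(g, zy$maternal, zy$paternal, 100,
                                       seed = 8))
  c2 <- generate_stage_tracks(g, stage_params("GV"), seed = 8)
  expect_equal(a, c2)
})
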