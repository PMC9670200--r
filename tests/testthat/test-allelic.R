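make_frag <- function(chrom = "chr1", start = 0, end = start + 200,
                      id = "f", mapq = 60, duplicate = FALSE,
                      snp_calls = data.frame(pos = numeric(),
                                             base = character())) {
  df <- data.frame(chrom = chrom, start = start, end = end, id = id,
                   mapq = mapq, duplicate = duplicate,
                   stringsAsFactors = FALSE)
  df$snp_calls <- list(snp_calls)
  df
}

test_that("fragment filters apply the exact length and MAPQ bounds", {
  frags <- rbind(make_frag(start = 0, end = 139, id = "short"),
                 make_frag(start = 0, end = 140, id = "len_ok"),
                 make_frag(start = 0, end = 200, id = "mapq29", mapq = 29),
                 make_frag(start = 0, end = 200, id = "mapq30", mapq = 30),
                 make_frag(start = 0, end = 200, id = "dup", duplicate = TRUE))
  kept <- filter_fragments(frags)
  expect_setequal(kept$id, c("len_ok", "mapq30"))
  expect_equal(attr(kept, "removed"),
               c(short = 1L, low_mapq = 1L, duplicate = 1L))
  ## duplicates retained when requested
  expect_true("dup" %in% filter_fragments(frags, drop_duplicates = FALSE)$id)
})

test_that("a toy fragment set survives filtering per hand enumeration", {
  set.seed(55)
  frags <- do.call(rbind, lapply(1:10, function(i)
    make_frag(start = 0, end = sample(c(100, 140, 300), 1), id = paste0("f", i),
              mapq = sample(c(10, 30, 60), 1),
              duplicate = sample(c(TRUE, FALSE), 1))))
  kept <- filter_fragments(frags)
  manual <- (frags$end - frags$start >= 140) & frags$mapq >= 30 &
    !frags$duplicate
  expect_equal(kept$id, frags$id[manual])
})

snp_tab <- data.frame(chrom = "chr1", pos = c(50, 150, 250),
                      maternal_base = c("A", "C", "G"),
                      paternal_base = c("T", "G", "A"),
                      stringsAsFactors = FALSE)

test_that("allele assignment follows the SNP evidence rule table", {
  f_m <- make_frag(start = 0, end = 200, snp_calls = data.frame(
    pos = 50, base = "A", stringsAsFactors = FALSE))
  f_none <- make_frag(start = 300, end = 500)
  f_conf <- make_frag(start = 0, end = 200, snp_calls = data.frame(
    pos = c(50, 150), base = c("A", "G"), stringsAsFactors = FALSE))
  f_err <- make_frag(start = 0, end = 200, snp_calls = data.frame(
    pos = 50, base = "C", stringsAsFactors = FALSE))  # matches neither
  calls <- assign_alleles(rbind(f_m, f_none, f_conf, f_err), snp_tab)
  expect_equal(calls$allele,
               c("maternal", "unassigned", "conflicting", "unassigned"))
  expect_equal(calls$n_maternal_evidence, c(1, 0, 1, 0))
  expect_equal(calls$n_paternal_evidence, c(0, 0, 1, 0))

  f_p2 <- make_frag(start = 0, end = 300, snp_calls = data.frame(
    pos = c(50, 150), base = c("T", "G"), stringsAsFactors = FALSE))
  expect_equal(assign_alleles(f_p2, snp_tab)$allele, "paternal")
})

test_that("synthetic fragments assign 100% concordantly with the ledger", {
  g <- test_genome()
  zy <- generate_stage_tracks(g, stage_params("zygote"), seed = 13)
  fr <- generate_allelic_fragments(g, zy$maternal, zy$paternal, 3000,
                                   seed = 13)
  kept <- filter_fragments(fr)
  calls <- assign_alleles(kept, g$snps)
  assigned <- calls$allele %in% c("maternal", "paternal")
  expect_gt(mean(assigned), 0.15)  # enough informative fragments to test
  expect_true(all(calls$allele[assigned] == kept$true_allele[assigned]))
  expect_true(all(calls$allele[!assigned] == "unassigned"))
})

test_that("allelic bias is signed maternal-high and mirrors on swap", {
  g <- small_genome()
  m <- uniform_track(4, g$chromosomes, 1000)
  expect_true(all(allelic_bias(m, m)$ratios == 0))

  p <- uniform_track(2, g$chromosomes, 1000)
  b <- allelic_bias(m, p, pseudocount = 0)
  expect_true(all(b$ratios == 1))  # M = 2P -> log2 ratio +1

  zy <- generate_stage_tracks(g, stage_params("zygote", noise_sd = 0),
                              seed = 2)
  bias <- allelic_bias(zy$maternal, zy$paternal)
  swapped <- allelic_bias(zy$paternal, zy$maternal)
  expect_equal(swapped$ratios, -bias$ratios)
  ## paternal asymmetry 2: the planted plateau ratio is exactly -1, and
  ## domain bins (the nonzero ratios) are paternal-high overall
  tm <- zy$truth[zy$truth$allele == "maternal", ][1, ]
  mm <- track_region_mean(zy$maternal, tm$chrom, tm$start, tm$end)
  pp <- track_region_mean(zy$paternal, tm$chrom, tm$start, tm$end)
  expect_equal(log2(mm / pp), -1)
  expect_lt(median(bias$ratios[bias$ratios != 0]), -0.9)
})

test_that("paired allelic comparison has the analytic degenerate limit", {
  g <- small_genome()
  m <- uniform_track(4, g$chromosomes, 1000)
  regions <- data.frame(chrom = "chr1", start = (0:9) * 1e4,
                        end = (0:9) * 1e4 + 5000)
  res <- compare_allelic_regions(m, m, regions, alternative = "greater")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 0.5)
  expect_true(res$degenerate)

  ## two-sided p is twice the smaller one-sided p
  set.seed(14)
  vals <- abs(rnorm(1000, 5, 1))
  a <- vec_track(vals, 1000, chrom_lengths = c(chr1 = 1e6))
  b <- vec_track(abs(vals + rnorm(1000, 0.2, 0.5)), 1000,
                 chrom_lengths = c(chr1 = 1e6))
  one <- compare_allelic_regions(a, b, regions, alternative = "greater")
  two <- compare_allelic_regions(a, b, regions, alternative = "two.sided")
  expect_equal(two$p_value, 2 * min(one$p_value, 1 - one$p_value))
  expect_false(one$degenerate)
  ## cross-check the non-degenerate path against stats::t.test
  tt <- t.test(one$regions$maternal, one$regions$paternal, paired = TRUE,
               alternative = "greater")
  expect_equal(one$t, unname(tt$statistic))
  expect_equal(one$p_value, tt$p.value)

  expect_error(compare_allelic_regions(m, m, regions[1, ]), "at least 2")
})

test_that("fragment coverage tracks count overlapping fragments per bin", {
  frags <- rbind(make_frag(start = 0, end = 1500, id = "a"),
                 make_frag(start = 500, end = 900, id = "b"),
                 make_frag(start = 2100, end = 2400, id = "c"))
  tr <- fragments_to_track(frags, c(chr1 = 3000), bin_size = 1000,
                           total_fragments = 3)
  ## counts per bin: 2, 1, 1 -> FPKM = count / (1 kb * 3e-6 M)
  expect_equal(tr$values$chr1, c(2, 1, 1) / (1 * 3 / 1e6))
})
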