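region_df <- function(chrom, mids, half = 500) {
  data.frame(chrom = chrom, start = mids - half, end = mids + half,
             stringsAsFactors = FALSE)
}

test_that("anchor pairs are the same-chromosome product within separation", {
  peaks <- region_df("chr1", c(105000, 405000))
  promoters <- region_df("chr1", c(1005000, 2005000, 3005000))
  pairs <- enumerate_anchor_pairs(peaks, promoters, 10000)
  expect_equal(nrow(pairs), 6)

  other <- region_df("chr2", 1005000)
  expect_equal(nrow(enumerate_anchor_pairs(peaks, other, 10000)), 0)

  ## pairs below min_sep are excluded; hand enumeration
  close_prom <- region_df("chr1", c(115000, 125000, 145000))
  pairs2 <- enumerate_anchor_pairs(peaks[1, ], close_prom, 10000,
                                   min_sep = 2)
  expect_equal(pairs2$bin_b, c(12, 14))  # bin 11 is 1 bin away -> dropped
  expect_error(enumerate_anchor_pairs(peaks[0, ], promoters, 10000), "empty")
})

test_that("pair enumeration deduplicates at bin resolution", {
  peaks <- region_df("chr1", c(105000, 105400))  # same 10 kb bin
  promoters <- region_df("chr1", 1005000)
  pairs <- enumerate_anchor_pairs(peaks, promoters, 10000)
  expect_equal(nrow(pairs), 1)
})

test_that("pile-up on a uniform matrix is flat near 1", {
  g <- test_genome()
  cm <- generate_contact_matrix(g, 10000, seed = 31, alpha = 0,
                                mean_count = 30)
  set.seed(31)
  n <- 250
  bin_a <- sample(20:300, n, replace = TRUE)
  pairs <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      bin_a = bin_a,
                      bin_b = bin_a + sample(5:60, n, replace = TRUE))
  pu <- pileup(cm, pairs, w = 5)
  expect_gt(pu$center_ratio, 0.9)
  expect_lt(pu$center_ratio, 1.1)
  expect_true(all(is.finite(pu$ratio)))
})

test_that("planted fold-8 loops give a center ratio near the fold", {
  g <- test_genome()
  set.seed(32)
  n <- 220
  bin_a <- sample(20:300, n, replace = TRUE)
  pairs <- unique(data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                             bin_a = bin_a,
                             bin_b = bin_a + sample(5:60, n, replace = TRUE)))
  loops <- cbind(pairs, fold = 8)
  cm <- generate_contact_matrix(g, 10000, loops, seed = 32, alpha = 0,
                                mean_count = 25)
  pu <- pileup(cm, pairs, w = 5)
  expect_gt(pu$center_ratio, 6)
  expect_lt(pu$center_ratio, 10)
})

test_that("pile-up is deterministic and invariant to pair order", {
  g <- small_genome()
  cm <- generate_contact_matrix(g, 10000, seed = 33, alpha = 0.5,
                                mean_count = 40)
  set.seed(33)
  bin_a <- sample(15:70, 40, replace = TRUE)
  pairs <- data.frame(chrom = "chr1", bin_a = bin_a,
                      bin_b = bin_a + sample(5:20, 40, replace = TRUE))
  pu1 <- pileup(cm, pairs, w = 3, seed = 5)
  pu2 <- pileup(cm, pairs[sample(nrow(pairs)), ], w = 3, seed = 5)
  expect_equal(pu1$ratio, pu2$ratio)
  pu3 <- pileup(cm, pairs, w = 3, seed = 6)
  expect_false(identical(pu1$ratio, pu3$ratio))
})

test_that("shifted controls preserve each pair's bin separation", {
  g <- small_genome()
  cm <- generate_contact_matrix(g, 10000, seed = 34, alpha = 1,
                                mean_count = 40)
  pairs <- data.frame(chrom = "chr1", bin_a = c(20, 35, 50),
                      bin_b = c(30, 60, 58))
  pu <- pileup(cm, pairs, w = 4, nshifts = 3, seed = 0,
               keep_controls = TRUE)
  ctl <- pu$control_pairs
  expect_equal(nrow(ctl), 9)
  expect_equal(ctl$bin_b - ctl$bin_a, ctl$real_b - ctl$real_a)
  ## control windows stay in bounds
  nb <- nrow(cm$matrices$chr1)
  expect_true(all(ctl$bin_a - 4 >= 0 & ctl$bin_b + 4 < nb))
})

test_that("out-of-bounds anchor windows are dropped and reported", {
  g <- small_genome()
  cm <- generate_contact_matrix(g, 10000, seed = 35, alpha = 0,
                                mean_count = 20)
  nb <- nrow(cm$matrices$chr1)
  pairs <- data.frame(chrom = "chr1", bin_a = c(1, 30), bin_b = c(11, 40))
  pu <- pileup(cm, pairs, w = 5)
  expect_equal(pu$n_pairs, 1)
  expect_equal(pu$n_dropped, 1)
  expect_error(pileup(cm, data.frame(chrom = "chrZ", bin_a = 1, bin_b = 9)),
               "absent")
})
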