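toy_sequence <- function(seed = 3, len = 2000) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

test_that("pseudo-chromosomes join instances with 200-N spacers", {
  seqs <- toy_sequence()
  reps <- data.frame(family = "fam", chrom = "chr1",
                     start = c(100, 600), end = c(200, 750),
                     strand = c("+", "+"), stringsAsFactors = FALSE)
  pg <- build_pseudo_genome(reps, seqs)
  expect_equal(nchar(pg$sequences[["fam"]]), 100 + 200 + 150)
  spacer <- substring(pg$sequences[["fam"]], 101, 300)
  expect_equal(spacer, strrep("N", 200))

  single <- build_pseudo_genome(reps[1, ], seqs)
  expect_equal(nchar(single$sequences[["fam"]]), 100)  # no flanking spacer

  empty <- reps[0, ]
  expect_error(build_pseudo_genome(empty, seqs), "no repeat family")
})

test_that("the coordinate map round-trips every base, both strands", {
  seqs <- toy_sequence()
  reps <- data.frame(family = "fam", chrom = "chr1",
                     start = c(100, 600), end = c(200, 750),
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  pg <- build_pseudo_genome(reps, seqs)
  pseudo <- pg$sequences[["fam"]]
  src <- map_pseudo_to_source(pg, "fam", 0:(nchar(pseudo) - 1))
  for (i in seq_len(nchar(pseudo))) {
    ch <- substring(pseudo, i, i)
    if (ch == "N") {
      expect_true(is.na(src$chrom[i]))
    } else {
      genome_base <- substring(seqs[[src$chrom[i]]], src$pos[i] + 1,
                               src$pos[i] + 1)
      expected <- if (src$strand[i] == "-") chartr("ACGT", "TGCA", genome_base)
                  else genome_base
      expect_equal(ch, expected)
    }
  }
})

test_that("minus-strand instances enter reverse-complemented", {
  seqs <- toy_sequence()
  reps <- data.frame(family = "fam", chrom = "chr1", start = 100, end = 130,
                     strand = "-", stringsAsFactors = FALSE)
  pg <- build_pseudo_genome(reps, seqs)
  fwd <- substring(seqs[["chr1"]], 101, 130)
  expect_equal(pg$sequences[["fam"]], revcomp(fwd))
})

test_that("quantification counts exact-substring hits with 1/k splitting", {
  pg <- list(sequences = c(famA = "ACGTACGTAAAGGGTTTCCC",
                           famB = paste0("TTTTTAAAGGGTTTGGGGG")),
             coord_map = NULL, annotation = NULL)
  class(pg) <- "PseudoGenome"
  counts <- quantify_repeat_reads(pg, c("ACGTACGT",   # unique to A
                                        "AAAGGGTTT",  # shared -> 1/2 each
                                        "CCCCCCCC"))  # matches nothing
  expect_equal(unname(counts[["famA"]]), 1.5)
  expect_equal(unname(counts[["famB"]]), 0.5)
  expect_equal(attr(counts, "unassigned"), 1)

  ## reverse-complement reads match too
  rc <- quantify_repeat_reads(pg, revcomp("ACGTACGT"))
  expect_equal(unname(rc[["famA"]]), 1)
})

test_that("reads straddling a spacer never match", {
  seqs <- toy_sequence()
  reps <- data.frame(family = "fam", chrom = "chr1",
                     start = c(100, 600), end = c(200, 750),
                     strand = "+", stringsAsFactors = FALSE)
  pg <- build_pseudo_genome(reps, seqs)
  ## genomic read running off the instance end: the pseudo-chromosome has Ns
  ## there, so it can never match
  run_off <- substring(seqs[["chr1"]], 191, 210)
  counts <- quantify_repeat_reads(pg, run_off)
  expect_equal(sum(counts), 0)
  expect_equal(attr(counts, "unassigned"), 1)
  ## and a read that itself contains N is never assigned
  counts_n <- quantify_repeat_reads(pg, paste0(strrep("N", 5),
                                               substring(seqs[["chr1"]], 101,
                                                         115)))
  expect_equal(attr(counts_n, "unassigned"), 1)
})

test_that("synthetic read quantification equals the ledger tally", {
  g <- test_genome()
  pg <- build_pseudo_genome(g$repeats, g$sequence)
  reads <- generate_repeat_reads(g, 1000, seed = 21)
  counts <- quantify_repeat_reads(pg, reads)
  tally <- table(factor(reads$true_family, levels = names(counts)))
  expect_equal(as.numeric(counts), as.numeric(tally))
  expect_equal(attr(counts, "unassigned"),
               sum(reads$true_family == "background"))
})

test_that("pseudo-genome FASTA and GTF outputs are readable", {
  seqs <- toy_sequence()
  reps <- data.frame(family = c("famA", "famB"), chrom = "chr1",
                     start = c(100, 600), end = c(200, 750),
                     strand = "+", stringsAsFactors = FALSE)
  pg <- build_pseudo_genome(reps, seqs)
  fa <- withr::local_tempfile(fileext = ".fa")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_pseudo_genome(pg, fa, gtf)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[["famA"]]), pg$sequences[["famA"]])
  ann <- read_gene_annotation(gtf)
  expect_equal(ann$gene_id, c("famA", "famB"))
  expect_equal(ann$end, unname(nchar(pg$sequences)))
})
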