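## Synthetic stage- and allele-resolved inputs with planted ground truth.
## The generator emulates the statistical structure the analysis assumes:
## hyperacetylated broad domains in GV oocytes and zygotes (paternal allele
## broader and higher in zygotes), sparse narrow domains in MII, canonical
## narrow peaks from the 2-cell stage on, allelic SNP evidence on fragments,
## distance-decay Hi-C backgrounds with planted promoter-enhancer loops, and
## stage-wise expression with minor/major ZGA, maternal-decay and
## Polycomb-target structure.

#' Default synthetic genome configuration
#'
#' A desk-scale stand-in for a mammalian genome: 2 chromosomes of 5 Mb, 200
#' non-overlapping genes, three retrotransposon-like repeat families, 17
#' maternal and 4 paternal imprinting control regions, and strain SNPs at a
#' mean spacing of 1 kb. Small enough that the full pipeline runs in minutes,
#' while every downstream module sees the structure it expects.
#'
#' @return A named list accepted by [generate_genome()].
#' @export
default_genome_config <- function() {
  list(
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    n_genes = 200,
    gene_length_range = c(5e3, 3e4),
    exons_per_gene = c(2, 6),
    cgi_fraction = 0.6,
    snp_spacing = 1000,
    repeat_families = list(
      MERVL = list(n = 20, length_range = c(400, 800)),
      MT2   = list(n = 15, length_range = c(300, 500)),
      LINE1 = list(n = 10, length_range = c(1000, 3000))),
    n_maternal_icrs = 17,
    n_paternal_icrs = 4,
    icr_length = 4000,
    with_sequence = TRUE
  )
}

#' Generate a synthetic genome model
#'
#' Deterministic for a fixed seed. Genes are placed without overlap (an
#' error is raised if the requested genes cannot be packed); repeats and
#' ICRs are placed independently. SNPs fall as a Poisson process with rate
#' `1/snp_spacing`; the maternal base is the reference base, the paternal
#' base a different one. Gene classes (minor/major ZGA, maternal decay,
#' PcG target, premature developmental) are assigned here and recorded in
#' the ground-truth ledger.
#'
#' @param config Configuration list, see [default_genome_config()]. Unknown
#'   keys are rejected.
#' @param seed Integer seed.
#' @return An object of class `GenomeModel`: list with `chromosomes`,
#'   `genes`, `repeats`, `icrs`, `snps`, `sequence` (or `NULL`), and `truth`
#'   (the ground-truth ledger).
#' @export
generate_genome <- function(config = default_genome_config(), seed = 1) {
  defaults <- default_genome_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown genome config key(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  lens <- config$chrom_lengths
  if (is.null(names(lens))) stop("chrom_lengths must be named")

  genes <- with_seed(substream_seed(seed, "genes"), {
    place_genes(config)
  })
  repeats <- with_seed(substream_seed(seed, "repeats"), {
    place_repeats(config)
  })
  icrs <- with_seed(substream_seed(seed, "icrs"), {
    place_icrs(config)
  })
  sequence <- if (isTRUE(config$with_sequence)) {
    with_seed(substream_seed(seed, "sequence"), {
      vapply(names(lens), function(chrom) {
        paste(sample(c("A", "C", "G", "T"), lens[[chrom]], replace = TRUE),
              collapse = "")
      }, character(1))
    })
  } else NULL
  snps <- with_seed(substream_seed(seed, "snps"), {
    place_snps(config, sequence)
  })
  classes <- with_seed(substream_seed(seed, "gene_classes"), {
    assign_gene_classes(genes$gene_id)
  })

  structure(
    list(chromosomes = lens, genes = genes, repeats = repeats, icrs = icrs,
         snps = snps, sequence = sequence,
         truth = list(gene_classes = classes, planted_domains = list(),
                      planted_loops = NULL),
         config = config, seed = seed),
    class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf(paste0("GenomeModel: %d chromosome(s), %g bp total\n",
                     "  %d genes, %d repeat instances (%d families), ",
                     "%d ICRs, %d SNPs\n"),
              length(x$chromosomes), sum(x$chromosomes), nrow(x$genes),
              nrow(x$repeats), length(unique(x$repeats$family)),
              nrow(x$icrs), nrow(x$snps)))
  invisible(x)
}

place_genes <- function(config) {
  lens <- config$chrom_lengths
  n <- config$n_genes
  if (n == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      tss = numeric(), tes = numeric(), cgi = logical(),
                      stringsAsFactors = FALSE))
  occupied <- lapply(lens, function(...) matrix(numeric(), ncol = 2))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:2000) {
      chrom <- sample(names(lens), 1, prob = lens)
      glen <- round(runif(1, config$gene_length_range[1],
                          config$gene_length_range[2]))
      if (glen + 2e4 > lens[[chrom]]) next
      start <- round(runif(1, 1e4, lens[[chrom]] - glen - 1e4))
      occ <- occupied[[chrom]]
      ## keep >= 5 kb between genes so promoter windows do not collide
      if (nrow(occ) && any(start < occ[, 2] + 5000 & start + glen + 5000 > occ[, 1]))
        next
      occupied[[chrom]] <- rbind(occ, c(start, start + glen))
      strand <- sample(c("+", "-"), 1)
      nex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      bounds <- sort(sample(seq(200, glen - 200, by = 100), 2 * (nex - 1)))
      es <- start + c(0, bounds[seq_along(bounds) %% 2 == 0])
      ee <- start + c(bounds[seq_along(bounds) %% 2 == 1], glen)
      out[[i]] <- list(chrom = chrom, start = start, end = start + glen,
                       strand = strand, es = list(es), ee = list(ee))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: cannot place ", n, " genes in this genome")
  }
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tes <- ifelse(genes$strand == "-", genes$start, genes$end)
  genes$cgi <- runif(n) < config$cgi_fraction
  genes$exon_starts <- lapply(out, function(g) g$es[[1]])
  genes$exon_ends <- lapply(out, function(g) g$ee[[1]])
  key <- match(genes$chrom, names(config$chrom_lengths))
  genes[order(key, genes$start), , drop = FALSE]
}

place_repeats <- function(config) {
  lens <- config$chrom_lengths
  fams <- config$repeat_families
  rows <- list()
  for (fam in names(fams)) {
    fc <- fams[[fam]]
    for (i in seq_len(fc$n)) {
      chrom <- sample(names(lens), 1, prob = lens)
      rlen <- round(runif(1, fc$length_range[1], fc$length_range[2]))
      start <- round(runif(1, 0, lens[[chrom]] - rlen))
      rows[[length(rows) + 1L]] <-
        data.frame(family = fam, chrom = chrom, start = start,
                   end = start + rlen, strand = sample(c("+", "-"), 1),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

place_icrs <- function(config) {
  lens <- config$chrom_lengths
  n_m <- config$n_maternal_icrs
  n_p <- config$n_paternal_icrs
  n <- n_m + n_p
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  start <- vapply(chrom, function(ch)
    round(runif(1, 0, lens[[ch]] - config$icr_length)), 0)
  data.frame(chrom = chrom, start = start, end = start + config$icr_length,
             parent_of_origin = c(rep("maternal", n_m), rep("paternal", n_p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

place_snps <- function(config, sequence) {
  lens <- config$chrom_lengths
  bases <- c("A", "C", "G", "T")
  rows <- lapply(names(lens), function(chrom) {
    n <- rpois(1, lens[[chrom]] / config$snp_spacing)
    pos <- sort(sample.int(lens[[chrom]], n) - 1L)
    mat <- if (!is.null(sequence))
      substring(sequence[[chrom]], pos + 1, pos + 1)
    else sample(bases, n, replace = TRUE)
    pat <- vapply(mat, function(b) sample(setdiff(bases, b), 1), "",
                  USE.NAMES = FALSE)
    data.frame(chrom = chrom, pos = pos, maternal_base = mat,
               paternal_base = pat, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

assign_gene_classes <- function(gene_ids) {
  sizes <- c(zygote_minor_zga = 6, early2c_minor_zga = 30, major_zga = 50,
             maternal_decay = 40, pcg_target = 20, developmental_premature = 10)
  n <- length(gene_ids)
  if (sum(sizes) > 0.8 * n)  # leave >= 20% unclassified background genes
    sizes <- floor(sizes * (0.8 * n) / sum(sizes))
  shuffled <- sample(gene_ids)
  classes <- list()
  at <- 1
  for (cl in names(sizes)) {
    k <- sizes[[cl]]
    classes[[cl]] <- sort(shuffled[seq.int(at, length.out = k)])
    at <- at + k
  }
  classes
}

## ---------------------------------------------------------------------------

#' Per-stage generator parameters
#'
#' Encodes the three-wave acetylation structure: `broad` stages (GV, zygote)
#' carry multi-10-kb hyperacetylated domains, `sparse` (MII) a handful of
#' narrow domains, `canonical` stages (2-cell onward, ESC) many narrow peaks.
#' `asymmetry` is the paternal/maternal factor applied in zygotes to both the
#' plateau level and the planted domain width, reflecting the broader and
#' higher paternal acetylation there.
#'
#' @param stage One of `"GV"`, `"MII"`, `"zygote"`, `"early2C"`, `"late2C"`,
#'   `"morula"`, `"ESC"`.
#' @param ... Overrides for individual fields (e.g. `noise_sd = 0`).
#' @return A `StageParams` list: `stage`, `domain_mode`, `n_domains`,
#'   `length_range` (bp), `bin_size` (the domain-calling bin the stage will
#'   be analysed at; domain boundaries are planted on this grid),
#'   `plateau` and `background` (FPKM), `noise_sd`, `asymmetry`.
#' @export
stage_params <- function(stage = c("GV", "MII", "zygote", "early2C", "late2C",
                                   "morula", "ESC"), ...) {
  stage <- match.arg(stage)
  base <- switch(stage,
    GV      = list(domain_mode = "broad", n_domains = 25,
                   length_range = c(20e3, 80e3), bin_size = 1000,
                   plateau = 8, background = 0.5, noise_sd = 0.5,
                   asymmetry = 1),
    MII     = list(domain_mode = "sparse", n_domains = 6,
                   length_range = c(2e3, 6e3), bin_size = 1000,
                   plateau = 8, background = 0.2, noise_sd = 0.2,
                   asymmetry = 1),
    zygote  = list(domain_mode = "broad", n_domains = 20,
                   length_range = c(20e3, 60e3), bin_size = 1000,
                   plateau = 8, background = 0.5, noise_sd = 0.5,
                   asymmetry = 2),
    early2C = list(domain_mode = "canonical", n_domains = 60,
                   length_range = c(1e3, 3e3), bin_size = 500,
                   plateau = 10, background = 0.5, noise_sd = 0.5,
                   asymmetry = 1),
    late2C  = list(domain_mode = "canonical", n_domains = 60,
                   length_range = c(1e3, 3e3), bin_size = 500,
                   plateau = 10, background = 0.5, noise_sd = 0.5,
                   asymmetry = 1),
    morula  = list(domain_mode = "canonical", n_domains = 50,
                   length_range = c(500, 2e3), bin_size = 500,
                   plateau = 10, background = 0.3, noise_sd = 0.3,
                   asymmetry = 1),
    ESC     = list(domain_mode = "canonical", n_domains = 80,
                   length_range = c(500, 2e3), bin_size = 500,
                   plateau = 10, background = 0.3, noise_sd = 0.3,
                   asymmetry = 1))
  over <- list(...)
  unknown <- setdiff(names(over), c(names(base)))
  if (length(unknown))
    stop("unknown StageParams field(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(base, over)
  params$stage <- stage
  if (params$plateau <= 3 || params$background >= 3)
    stop("StageParams requires plateau > 3 > background")
  if (any(params$length_range <= 0)) stop("length ranges must be positive")
  structure(params, class = "StageParams")
}

#' Generate maternal, paternal and combined stage tracks
#'
#' Plants non-overlapping acetylation domains on the stage's calling-bin
#' grid, gives the paternal allele `asymmetry`-fold higher plateaus over
#' `asymmetry`-fold wider intervals (centered extension), adds truncated
#' Gaussian bin noise shared between the alleles (so alleles are identical
#' when `asymmetry = 1`), and returns the combined track as the mean of the
#' two allelic tracks. The planted intervals are returned as ground truth.
#'
#' @param genome A [generate_genome()] model.
#' @param params A [stage_params()] object.
#' @param seed Integer seed.
#' @param track_bin Bin size of the generated tracks (bp); domain boundaries
#'   are planted on the coarser `params$bin_size` grid, which must be a
#'   multiple of `track_bin`.
#' @return A list of class `stage_tracks`: `maternal`, `paternal`,
#'   `combined` ([signal_track()]s) and `truth` (data frame of planted
#'   domains with `chrom`, `start`, `end`, `allele`, `level`; allele
#'   `"both"` rows give the union interval seen by the combined track).
#' @export
generate_stage_tracks <- function(genome, params, seed = 1,
                                  track_bin = 100) {
  stopifnot(inherits(params, "StageParams"))
  if (params$bin_size %% track_bin != 0)
    stop("params$bin_size must be a multiple of track_bin")
  lens <- genome$chromosomes
  bs <- params$bin_size
  asym <- params$asymmetry

  domains <- with_seed(substream_seed(seed, "domains", params$stage), {
    place_stage_domains(lens, params)
  })
  noise <- with_seed(substream_seed(seed, "noise", params$stage), {
    lapply(names(lens), function(chrom)
      rnorm(ceiling(lens[[chrom]] / track_bin), 0, params$noise_sd))
  })
  names(noise) <- names(lens)

  build <- function(allele) {
    values <- lapply(names(lens), function(chrom) {
      v <- rep(params$background, ceiling(lens[[chrom]] / track_bin))
      d <- domains[domains$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        if (allele == "maternal") {
          b0 <- d$start[i] %/% track_bin; b1 <- d$end[i] %/% track_bin
          v[(b0 + 1):b1] <- params$plateau
        } else {
          b0 <- d$pat_start[i] %/% track_bin; b1 <- d$pat_end[i] %/% track_bin
          v[(b0 + 1):b1] <- params$plateau * asym
        }
      }
      pmax(0, v + noise[[chrom]])
    })
    names(values) <- names(lens)
    signal_track(values, track_bin, chrom_lengths = lens,
                 stage = params$stage, allele = allele)
  }
  maternal <- build("maternal")
  paternal <- build("paternal")
  combined_values <- lapply(names(lens), function(chrom)
    (maternal$values[[chrom]] + paternal$values[[chrom]]) / 2)
  names(combined_values) <- names(lens)
  combined <- signal_track(combined_values, track_bin, chrom_lengths = lens,
                           stage = params$stage, allele = "both")

  truth <- rbind(
    data.frame(chrom = domains$chrom, start = domains$start,
               end = domains$end, allele = "maternal",
               level = params$plateau, stringsAsFactors = FALSE),
    data.frame(chrom = domains$chrom, start = domains$pat_start,
               end = domains$pat_end, allele = "paternal",
               level = params$plateau * asym, stringsAsFactors = FALSE),
    data.frame(chrom = domains$chrom,
               start = pmin(domains$start, domains$pat_start),
               end = pmax(domains$end, domains$pat_end), allele = "both",
               level = params$plateau * (1 + asym) / 2,
               stringsAsFactors = FALSE))
  truth$stage <- params$stage
  structure(list(maternal = maternal, paternal = paternal,
                 combined = combined, truth = truth, params = params),
            class = "stage_tracks")
}

## choose non-overlapping maternal intervals on the bin grid, plus the
## centered paternal extension; envelopes are kept >= 4 bins apart so planted
## domains never merge during calling (merge gap is 2 bins, inclusive)
place_stage_domains <- function(lens, params) {
  bs <- params$bin_size
  asym <- params$asymmetry
  min_gap <- 4 * bs
  occupied <- lapply(lens, function(...) matrix(numeric(), ncol = 2))
  rows <- list()
  for (i in seq_len(params$n_domains)) {
    placed <- FALSE
    for (try in 1:2000) {
      chrom <- sample(names(lens), 1, prob = lens)
      w <- max(bs, bs * round(runif(1, params$length_range[1],
                                    params$length_range[2]) / bs))
      pw <- max(w, bs * round(w * asym / bs))
      ext <- bs * ceiling((pw - w) / 2 / bs)
      start <- bs * round(runif(1, ext + bs, lens[[chrom]] - w - ext - bs) / bs)
      env <- c(start - ext, start + w + ext)
      occ <- occupied[[chrom]]
      if (nrow(occ) && any(env[1] - min_gap < occ[, 2] &
                           env[2] + min_gap > occ[, 1])) next
      occupied[[chrom]] <- rbind(occ, env)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + w,
        pat_start = env[1], pat_end = env[2], stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: cannot place ", params$n_domains,
           " domains for stage ", params$stage)
  }
  out <- do.call(rbind, rows)
  key <- match(out$chrom, names(lens))
  out[order(key, out$start), , drop = FALSE]
}

## ---------------------------------------------------------------------------

#' Generate allele-labelled fragments from allelic tracks
#'
#' Fragment starts are sampled proportionally to the intensity of the true
#' allele's track; every SNP a fragment overlaps reports the true allele's
#' base. A configurable fraction of fragments is generated short (< 140 bp),
#' low-MAPQ (< 30) or duplicate-flagged, to exercise the upstream filters.
#'
#' @param genome A [generate_genome()] model (provides SNPs).
#' @param track_m,track_p Maternal and paternal [signal_track()]s.
#' @param n Number of fragments (> 0).
#' @param seed Integer seed.
#' @param frag_len_range Length range (bp) of proper fragments.
#' @param contaminant_frac Fraction with sub-140 bp lengths.
#' @param low_mapq_frac Fraction with MAPQ below 30.
#' @param dup_rate Fraction flagged as duplicates.
#' @return Fragment data frame (`chrom`, `start`, `end`, `id`, `mapq`,
#'   `duplicate`, list-column `snp_calls`) plus the truth column
#'   `true_allele`.
#' @export
generate_allelic_fragments <- function(genome, track_m, track_p, n, seed = 1,
                                       frag_len_range = c(140, 500),
                                       contaminant_frac = 0.05,
                                       low_mapq_frac = 0.05,
                                       dup_rate = 0.05) {
  if (n <= 0) stop("n must be positive")
  lens <- genome$chromosomes
  snps <- genome$snps
  with_seed(substream_seed(seed, "fragments"), {
    mass_m <- sum(vapply(track_m$values, sum, 0))
    mass_p <- sum(vapply(track_p$values, sum, 0))
    allele <- ifelse(runif(n) < mass_m / (mass_m + mass_p),
                     "maternal", "paternal")
    len <- round(runif(n, frag_len_range[1], frag_len_range[2]))
    short <- runif(n) < contaminant_frac
    len[short] <- round(runif(sum(short), 50, 139))
    mapq <- rep(60, n)
    low <- runif(n) < low_mapq_frac
    mapq[low] <- floor(runif(sum(low), 0, 30))
    duplicate <- runif(n) < dup_rate

    ## per-allele cumulative bin weights for position sampling
    sample_positions <- function(track, k) {
      w <- unlist(track$values, use.names = FALSE)
      nb <- vapply(track$values, length, 0L)
      bin <- sample.int(length(w), k, replace = TRUE, prob = w)
      chrom_idx <- findInterval(bin - 1L, cumsum(nb), left.open = FALSE) + 1L
      chrom <- names(track$values)[chrom_idx]
      local_bin <- bin - c(0, cumsum(nb))[chrom_idx] - 1L
      pos <- local_bin * track$bin_size +
        floor(runif(k, 0, track$bin_size))
      data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }
    out <- data.frame(chrom = character(n), start = numeric(n),
                      end = numeric(n), stringsAsFactors = FALSE)
    for (al in c("maternal", "paternal")) {
      idx <- which(allele == al)
      if (!length(idx)) next
      ps <- sample_positions(if (al == "maternal") track_m else track_p,
                             length(idx))
      start <- pmax(0, pmin(ps$pos, lens[ps$chrom] - len[idx]))
      out$chrom[idx] <- ps$chrom
      out$start[idx] <- start
      out$end[idx] <- start + len[idx]
    }
    out$id <- sprintf("frag%06d", seq_len(n))
    out$mapq <- mapq
    out$duplicate <- duplicate
    out$true_allele <- allele
    out$snp_calls <- lapply(seq_len(n), function(i) {
      s <- snps[snps$chrom == out$chrom[i] & snps$pos >= out$start[i] &
                snps$pos < out$end[i], , drop = FALSE]
      base <- if (allele[i] == "maternal") s$maternal_base else s$paternal_base
      data.frame(pos = s$pos, base = base, stringsAsFactors = FALSE)
    })
    out
  })
}

## ---------------------------------------------------------------------------

#' Generate a synthetic Hi-C contact matrix with planted loops
#'
#' Background counts follow a distance-decay mean
#' `mean_count / (1 + |i - j|)^alpha`, Poisson-sampled symmetrically; pixels
#' listed in `loops` have their mean multiplied by the loop fold before
#' sampling.
#'
#' @param genome A [generate_genome()] model.
#' @param resolution Bin width in bp.
#' @param loops Optional data frame with `chrom`, `bin_a`, `bin_b`, `fold`.
#' @param seed Integer seed.
#' @param alpha Distance-decay exponent (0 = flat background).
#' @param mean_count Poisson mean at distance 0.
#' @return A `ContactMatrix` (see [contact_matrix()]).
#' @export
generate_contact_matrix <- function(genome, resolution = 10000, loops = NULL,
                                    seed = 1, alpha = 1, mean_count = 50) {
  lens <- genome$chromosomes
  with_seed(substream_seed(seed, "contacts"), {
    matrices <- lapply(names(lens), function(chrom) {
      nb <- ceiling(lens[[chrom]] / resolution)
      d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
      mu <- mean_count / (1 + d)^alpha
      if (!is.null(loops)) {
        lp <- loops[loops$chrom == chrom, , drop = FALSE]
        if (nrow(lp) && (any(lp$bin_a >= nb) || any(lp$bin_b >= nb)))
          stop("loop anchor outside genome on ", chrom)
        for (i in seq_len(nrow(lp))) {
          mu[lp$bin_a[i] + 1L, lp$bin_b[i] + 1L] <-
            mu[lp$bin_a[i] + 1L, lp$bin_b[i] + 1L] * lp$fold[i]
          mu[lp$bin_b[i] + 1L, lp$bin_a[i] + 1L] <-
            mu[lp$bin_b[i] + 1L, lp$bin_a[i] + 1L] * lp$fold[i]
        }
      }
      m <- matrix(0, nb, nb)
      up <- upper.tri(m, diag = TRUE)
      m[up] <- rpois(sum(up), mu[up])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    names(matrices) <- names(lens)
    contact_matrix(matrices, resolution)
  })
}

## ---------------------------------------------------------------------------

#' Generate stage expression and differential-expression tables
#'
#' Produces a per-gene FPKM matrix over stages (MII, zygote, early 2-cell,
#' late 2-cell, 4-cell, morula), the pairwise DE tables the gene-set filters
#' consume, DRB-transcription-inhibition contrasts at zygote and early
#' 2-cell, and promoter H3K27me3 flags. Fold changes and adjusted p-values
#' are synthesized consistently with the planted gene classes: genes truly
#' changed in a contrast draw `padj` log-uniform in `[1e-8, cutoff/10]`,
#' null genes in `[0.2, 1]`, so the filters (not a DE estimator) are what is
#' being tested.
#'
#' @param genome A [generate_genome()] model with gene classes in its ledger.
#' @param seed Integer seed.
#' @param noise_sd Multiplicative log-normal noise SD on FPKM values
#'   (0 = class-exact tables).
#' @return List with `expression` (genes x stages FPKM matrix), `de`
#'   (named list of DE data frames; names encode the contrast, `b` vs `a`),
#'   and `promoter_h3k27me3` (named logical vector).
#' @export
generate_expression_tables <- function(genome, seed = 1, noise_sd = 0) {
  classes <- genome$truth$gene_classes
  ids <- genome$genes$gene_id
  stages <- c("MII", "zygote", "early2C", "late2C", "fourC", "morula")
  with_seed(substream_seed(seed, "expression"), {
    expr <- matrix(5, nrow = length(ids), ncol = length(stages),
                   dimnames = list(ids, stages))
    set_cls <- function(cl, levels) {
      if (!length(classes[[cl]])) return()
      expr[classes[[cl]], ] <<- matrix(levels, nrow = length(classes[[cl]]),
                                       ncol = length(stages), byrow = TRUE)
    }
    set_cls("zygote_minor_zga",  c(0.5, 4, 4, 4, 4, 4))
    set_cls("early2c_minor_zga", c(0.5, 0.5, 4, 4, 4, 4))
    set_cls("major_zga",         c(1, 1, 1, 8, 8, 8))
    set_cls("maternal_decay",    c(20, 4, 2, 1, 0.5, 0.5))
    set_cls("pcg_target",        rep(0.01, 6))
    set_cls("developmental_premature", rep(0.02, 6))
    if (noise_sd > 0)
      expr <- expr * matrix(exp(rnorm(length(expr), 0, noise_sd)),
                            nrow = nrow(expr))

    marked <- setNames(ids %in% classes$pcg_target, ids)
    ## some expressed genes are also H3K27me3-marked; the FPKM filter must
    ## exclude them
    candidates <- setdiff(ids, unlist(classes))
    marked[sample(candidates, min(10, length(candidates)))] <- TRUE

    de_table <- function(stage_a, stage_b, true_set, fc_padj_max) {
      a <- expr[, stage_a]
      b <- expr[, stage_b]
      is_true <- ids %in% true_set
      padj <- ifelse(is_true,
                     10^runif(length(ids), -8, log10(fc_padj_max)),
                     runif(length(ids), 0.2, 1))
      data.frame(gene_id = ids, mean_fpkm_a = a, mean_fpkm_b = b,
                 log2fc = log2((b + 1e-3) / (a + 1e-3)), padj = padj,
                 stringsAsFactors = FALSE)
    }
    drb_table <- function(stage, true_set, fc_padj_max) {
      ctrl <- expr[, stage]
      drb <- ctrl
      is_true <- ids %in% true_set
      drb[is_true] <- ctrl[is_true] / 4  # transcription-dependent genes drop
      padj <- ifelse(is_true,
                     10^runif(length(ids), -8, log10(fc_padj_max)),
                     runif(length(ids), 0.2, 1))
      data.frame(gene_id = ids, mean_fpkm_a = ctrl, mean_fpkm_b = drb,
                 log2fc = log2((drb + 1e-3) / (ctrl + 1e-3)), padj = padj,
                 stringsAsFactors = FALSE)
    }
    decay <- classes$maternal_decay
    list(
      expression = expr,
      de = list(
        late2c_vs_zygote = de_table("zygote", "late2C", classes$major_zga, 1e-3),
        zygote_vs_mii    = de_table("MII", "zygote", decay, 1e-3),
        early2c_vs_mii   = de_table("MII", "early2C", decay, 1e-3),
        late2c_vs_mii    = de_table("MII", "late2C", decay, 1e-3),
        fourc_vs_mii     = de_table("MII", "fourC", decay, 1e-3),
        drb_zygote       = drb_table("zygote", classes$zygote_minor_zga, 5e-3),
        drb_early2c      = drb_table("early2C", classes$early2c_minor_zga, 5e-3)),
      promoter_h3k27me3 = marked)
  })
}

## ---------------------------------------------------------------------------

#' Generate error-free reads from repeat instances
#'
#' Draws reads wholly inside repeat instances (family-labelled, random
#' strand) plus a configurable fraction of background reads from non-repeat
#' genome, for testing repeat pseudo-genome quantification.
#'
#' @param genome A [generate_genome()] model with sequence.
#' @param n Number of reads.
#' @param read_len Read length (bp); instances shorter than this are skipped.
#' @param background_frac Fraction of reads from non-repeat background.
#' @param seed Integer seed.
#' @return Data frame with `read` (sequence) and `true_family`
#'   (`"background"` for background reads).
#' @export
generate_repeat_reads <- function(genome, n, read_len = 50,
                                  background_frac = 0.1, seed = 1) {
  if (is.null(genome$sequence))
    stop("genome was generated without sequence")
  reps <- genome$repeats[genome$repeats$end - genome$repeats$start >= read_len, ,
                         drop = FALSE]
  with_seed(substream_seed(seed, "repeat_reads"), {
    is_bg <- runif(n) < background_frac
    inst <- sample.int(nrow(reps), n, replace = TRUE,
                       prob = reps$end - reps$start)
    reads <- character(n)
    fam <- character(n)
    for (i in seq_len(n)) {
      if (is_bg[i]) {
        repeat {
          chrom <- sample(names(genome$chromosomes), 1,
                          prob = genome$chromosomes)
          start <- floor(runif(1, 0, genome$chromosomes[[chrom]] - read_len))
          hit <- any(reps$chrom == chrom & reps$start < start + read_len &
                     reps$end > start)
          if (!hit) break
        }
        fam[i] <- "background"
      } else {
        j <- inst[i]
        chrom <- reps$chrom[j]
        start <- floor(runif(1, reps$start[j], reps$end[j] - read_len))
        fam[i] <- reps$family[j]
      }
      s <- substring(genome$sequence[[chrom]], start + 1, start + read_len)
      if (runif(1) < 0.5) s <- revcomp(s)
      reads[i] <- s
    }
    data.frame(read = reads, true_family = fam, stringsAsFactors = FALSE)
  })
}
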