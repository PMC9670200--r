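## End-to-end orchestration of the synthetic study: generate a genome and
## stage/allele tracks, scale them against the ESC reference, call domains,
## cluster stage transitions, run the allelic, repeat, gene-set and pile-up
## analyses, and assemble a machine-readable report with recovery metrics
## against the planted ground truth.

#' One-decimal percentage of a count
#'
#' The reporting convention used throughout: `round(100 * count / total, 1)`
#' (e.g. 416 of 558 is 74.6).
#'
#' @param count Numerator.
#' @param total Denominator (> 0).
#' @return Percentage rounded to one decimal.
#' @export
percent_of <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  round(100 * count / total, 1)
}

#' Exact-boundary domain recovery against planted truth
#'
#' @param domains Called domains (`chrom`, `start`, `end`).
#' @param truth Planted intervals (`chrom`, `start`, `end`).
#' @param tol Boundary tolerance in bp (0 = exact).
#' @return List with `precision`, `recall` (fraction of called/planted
#'   intervals whose both boundaries match within `tol`), and
#'   `boundary_within_tol` (fraction of planted boundaries matched by some
#'   called boundary within `tol`).
#' @export
domain_recovery <- function(domains, truth, tol = 0) {
  match_iv <- function(a, b) {  # rows of a with an interval match in b
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & abs(b$start - a$start[i]) <= tol &
          abs(b$end - a$end[i]) <= tol)
    }, logical(1))
  }
  boundary_hit <- function(side) {
    vapply(seq_len(nrow(truth)), function(i) {
      any(domains$chrom == truth$chrom[i] &
          abs(domains[[side]] - truth[[side]][i]) <= tol)
    }, logical(1))
  }
  list(
    precision = if (nrow(domains)) mean(match_iv(domains, truth)) else NA_real_,
    recall = if (nrow(truth)) mean(match_iv(truth, domains)) else NA_real_,
    boundary_within_tol = if (nrow(truth))
      mean(c(boundary_hit("start"), boundary_hit("end"))) else NA_real_)
}

#' Default pipeline configuration
#'
#' Every analysis parameter appears as a named key at its standard value:
#' calling bins 1000/500 bp with threshold 3 and merge gap 2 bins, top-3,000
#' promoter scaling with a +-2 kb window and ESC reference, fragment
#' filters of at least 140 bp and MAPQ 30, allelic bias at 1 kb with
#' pseudocount 0.5,
#' promoter/distal peak cutoffs 1 kb / 2.5 kb, Hi-C pile-up at 10 kb with 1
#' shifted control and shift seed 0, and gene-set cutoffs FC 2 / padj 0.05
#' (minor ZGA), FC 4 / padj 0.01 (major ZGA, maternal decay), mean FPKM 1
#' and PcG FPKM < 0.1.
#'
#' @return Nested named list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    genome = default_genome_config(),
    stages = c("GV", "MII", "zygote", "early2C", "late2C", "morula", "ESC"),
    stage_overrides = list(),
    normalization = list(reference = "ESC", top_n = 3000,
                         promoter_flank = 2000),
    domain_calling = list(threshold = 3, merge_gap_bins = 2),
    fragments = list(n = 20000, min_len = 140, min_mapq = 30,
                     drop_duplicates = TRUE),
    allelic = list(bias_bin = 1000, pseudocount = 0.5),
    peaks = list(promoter_dist = 1000, distal_dist = 2500,
                 lost_ratio = 0.5, gain_ratio = 2),
    repeats = list(n_reads = 1000, read_len = 50, background_frac = 0.1),
    hic = list(resolution = 10000, w = 5, nshifts = 1, shift_seed = 0,
               loop_fold = 8, mean_count = 50, alpha = 0,
               min_sep = 2, max_sep = 30),
    gene_sets = list(minor_fc = 2, minor_padj = 0.05, major_fc = 4,
                     major_padj = 0.01, min_mean_fpkm = 1, pcg_fpkm_max = 0.1)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values are overlaid on [default_pipeline_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_pipeline_config(user)
}

merge_pipeline_config <- function(user) {
  defaults <- default_pipeline_config()
  ## free-form sections keyed by user-chosen names (stages, families, chroms)
  dynamic <- c("stage_overrides", "repeat_families", "chrom_lengths")
  check <- function(u, d, where) {
    if (!is.list(u)) return()
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown config key(s) ", where,
           paste(unknown, collapse = ", "))
    for (k in setdiff(names(u), dynamic))
      if (is.list(d[[k]])) check(u[[k]], d[[k]], paste0(where, k, "."))
  }
  check(user, defaults, "")
  utils::modifyList(defaults, user)
}

#' Run the full synthetic study
#'
#' Generates the genome and every stage, scales tracks against the ESC
#' reference, calls per-stage domains (combined and per allele), clusters
#' the GV-to-zygote domain transitions, performs allelic fragment analysis
#' in zygotes, repeat pseudo-genome quantification, gene-set derivation,
#' peak classification with a modelled acetyltransferase-inhibition
#' response, and promoter-enhancer pile-up, then returns a report with
#' recovery metrics against the planted truth. Deterministic for a fixed
#' seed.
#'
#' @param config Configuration list (see [default_pipeline_config()];
#'   partial lists are overlaid on the defaults).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param outdir Optional directory for output tables (domain BED, scale
#'   factors, gene sets, report JSON, ground-truth ledger).
#' @return A `run_report` list; see the vignette for the layout.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  config <- merge_pipeline_config(config)
  if (is.null(seed)) seed <- config$seed
  report <- list(seed = seed)

  genome <- generate_genome(config$genome, seed)
  stages <- config$stages
  tracks <- list()
  truths <- list()
  for (stage in stages) {
    over <- config$stage_overrides[[stage]]
    params <- do.call(stage_params, c(list(stage = stage), over))
    st <- generate_stage_tracks(genome, params, seed)
    tracks[[stage]] <- st
    truths[[stage]] <- st$truth
  }
  genome$truth$planted_domains <- truths

  ## cross-stage scaling against the reference
  norm <- config$normalization
  combined <- lapply(tracks, `[[`, "combined")
  factors <- suppressWarnings(
    scale_factor_table(combined, genome$genes, reference = norm$reference,
                       top_n = min(norm$top_n, nrow(genome$genes)),
                       flank = norm$promoter_flank))
  report$scale_factors <- factors
  scaled <- list()
  for (stage in stages) {
    f <- factors$scale_factor[factors$stage == stage]
    scaled[[stage]] <- list(
      combined = apply_scale(tracks[[stage]]$combined, f),
      maternal = apply_scale(tracks[[stage]]$maternal, f),
      paternal = apply_scale(tracks[[stage]]$paternal, f))
  }

  ## per-stage domain calling, combined and per allele
  dc <- config$domain_calling
  domains <- list()
  report$domains <- list()
  for (stage in stages) {
    bs <- tracks[[stage]]$params$bin_size
    gap <- dc$merge_gap_bins * bs
    dom <- list(
      combined = call_domains(scaled[[stage]]$combined, bs, dc$threshold, gap),
      maternal = call_domains(scaled[[stage]]$maternal, bs, dc$threshold, gap),
      paternal = call_domains(scaled[[stage]]$paternal, bs, dc$threshold, gap))
    domains[[stage]] <- dom
    truth_both <- truths[[stage]][truths[[stage]]$allele == "both", ]
    report$domains[[stage]] <- list(
      n = nrow(dom$combined),
      size = domain_size_stats(dom$combined),
      total_bases = sum(dom$combined$end - dom$combined$start),
      maternal_bases = sum(dom$maternal$end - dom$maternal$start),
      paternal_bases = sum(dom$paternal$end - dom$paternal$start),
      recovery_exact = domain_recovery(dom$combined, truth_both, tol = 0),
      composition = as.list(annotate_domain_bases(dom$combined, genome$genes,
                                                  norm$promoter_flank)))
  }

  ## GV-to-zygote transition clustering over the pooled broad-stage domains
  trans_stages <- intersect(c("GV", "MII", "zygote"), stages)
  if (length(trans_stages) >= 2) {
    pooled <- unique(do.call(rbind, lapply(trans_stages, function(s)
      domains[[s]]$combined[, c("chrom", "start", "end")])))
    mat <- domain_signal_matrix(pooled,
                                lapply(scaled[trans_stages], `[[`, "combined"))
    cl <- cluster_domain_transitions(mat, k = 3, seed = seed)
    report$transitions <- list(n_domains = nrow(pooled),
                               cluster_sizes = tabulate(cl$labels, 3),
                               tot_withinss = cl$tot_withinss)
  }

  ## allelic analysis in zygotes
  if ("zygote" %in% stages) {
    fr_cfg <- config$fragments
    frags <- generate_allelic_fragments(genome, tracks$zygote$maternal,
                                        tracks$zygote$paternal,
                                        fr_cfg$n, seed)
    kept <- filter_fragments(frags, fr_cfg$min_len, fr_cfg$min_mapq,
                             fr_cfg$drop_duplicates)
    calls <- assign_alleles(kept, genome$snps)
    assigned <- calls$allele %in% c("maternal", "paternal")
    concord <- calls$allele[assigned] == kept$true_allele[assigned]
    al_cfg <- config$allelic
    track_m <- fragments_to_track(kept[calls$allele == "maternal", ],
                                  genome$chromosomes, al_cfg$bias_bin,
                                  total_fragments = nrow(kept),
                                  allele = "maternal", stage = "zygote")
    track_p <- fragments_to_track(kept[calls$allele == "paternal", ],
                                  genome$chromosomes, al_cfg$bias_bin,
                                  total_fragments = nrow(kept),
                                  allele = "paternal", stage = "zygote")
    bias <- allelic_bias(track_m, track_p, al_cfg$bias_bin,
                         al_cfg$pseudocount)
    icrs_m <- genome$icrs[genome$icrs$parent_of_origin == "maternal", ]
    icr_cmp <- compare_allelic_regions(track_m, track_p, icrs_m,
                                       alternative = "less")
    report$allelic <- list(
      n_fragments = fr_cfg$n, n_kept = nrow(kept),
      removed = as.list(attr(kept, "removed")),
      assignment = as.list(table(calls$allele)),
      assigned_concordance_pct = percent_of(sum(concord), length(concord)),
      bias_summary = as.list(bias$summary),
      maternal_icr = list(n = nrow(icrs_m), t = icr_cmp$t,
                          p_value = icr_cmp$p_value,
                          alternative = icr_cmp$alternative))
  }

  ## repeat pseudo-genome quantification
  rp_cfg <- config$repeats
  pg <- build_pseudo_genome(genome$repeats, genome$sequence)
  reads <- generate_repeat_reads(genome, rp_cfg$n_reads, rp_cfg$read_len,
                                 rp_cfg$background_frac, seed)
  counts <- quantify_repeat_reads(pg, reads)
  tally <- table(factor(reads$true_family, levels = names(counts)))
  report$repeats <- list(
    families = names(counts), counts = as.numeric(counts),
    unassigned = attr(counts, "unassigned"),
    matches_truth = isTRUE(all.equal(as.numeric(counts), as.numeric(tally))))

  ## gene sets
  gs_cfg <- config$gene_sets
  tables <- generate_expression_tables(genome, seed)
  sets <- list(
    zygote_minor_zga = define_minor_zga(tables$de$drb_zygote, "zygote",
      gs_cfg$minor_fc, gs_cfg$minor_padj, gs_cfg$min_mean_fpkm),
    early2c_minor_zga = define_minor_zga(tables$de$drb_early2c, "early2C",
      gs_cfg$minor_fc, gs_cfg$minor_padj, gs_cfg$min_mean_fpkm),
    major_zga = define_major_zga(tables$de$late2c_vs_zygote,
      gs_cfg$major_fc, gs_cfg$major_padj, gs_cfg$min_mean_fpkm),
    maternal_decay = define_maternal_decay(tables$de[c(
      "zygote_vs_mii", "early2c_vs_mii", "late2c_vs_mii", "fourc_vs_mii")],
      gs_cfg$major_fc, gs_cfg$major_padj, gs_cfg$min_mean_fpkm),
    pcg_target = define_pcg_targets(tables$promoter_h3k27me3,
                                    tables$expression, gs_cfg$pcg_fpkm_max))
  recovery <- vapply(names(sets), function(nm)
    identical(sets[[nm]]$gene_ids,
              sort(genome$truth$gene_classes[[nm]])), logical(1))
  report$gene_sets <- list(sizes = lapply(sets, function(s)
    length(s$gene_ids)), ledger_recovered = as.list(recovery))

  ## peak classification and modelled acetyltransferase-inhibition response
  if ("early2C" %in% stages) {
    pk_cfg <- config$peaks
    peaks <- domains$early2C$combined
    classes <- classify_peaks_by_tss(peaks, genome$genes,
                                     pk_cfg$promoter_dist, pk_cfg$distal_dist)
    treated <- scaled$early2C$combined
    for (i in which(classes == "distal")) {  # inhibitor removes distal signal
      bs <- treated$bin_size
      b0 <- peaks$start[i] %/% bs + 1L
      b1 <- min(peaks$end[i] %/% bs, length(treated$values[[peaks$chrom[i]]]))
      treated$values[[peaks$chrom[i]]][b0:b1] <-
        treated$values[[peaks$chrom[i]]][b0:b1] * 0.1
    }
    response <- classify_peak_response(peaks, scaled$early2C$combined, treated,
                                       pk_cfg$lost_ratio, pk_cfg$gain_ratio)
    n_distal <- sum(classes == "distal")
    n_prom <- sum(classes == "promoter")
    report$peaks <- list(
      n = nrow(peaks),
      class_counts = as.list(table(classes)),
      distal_lost_pct = if (n_distal)
        percent_of(sum(response == "lost" & classes == "distal"), n_distal)
        else NA,
      promoter_unaffected_or_enhanced_pct = if (n_prom)
        percent_of(sum(response != "lost" & classes == "promoter"), n_prom)
        else NA)
  }

  ## promoter-enhancer pile-up with planted loops, PcG promoters as control
  hic_cfg <- config$hic
  zga_prom <- promoter_regions(genome, genome$truth$gene_classes$major_zga,
                               norm$promoter_flank)
  pcg_prom <- promoter_regions(genome, genome$truth$gene_classes$pcg_target,
                               norm$promoter_flank)
  peaks_df <- distal_partner_peaks(genome, zga_prom, hic_cfg)
  zga_pairs <- enumerate_anchor_pairs(peaks_df, zga_prom, hic_cfg$resolution,
                                      hic_cfg$min_sep, hic_cfg$max_sep)
  loops <- data.frame(chrom = zga_pairs$chrom, bin_a = zga_pairs$bin_a,
                      bin_b = zga_pairs$bin_b, fold = hic_cfg$loop_fold)
  contacts <- generate_contact_matrix(genome, hic_cfg$resolution, loops, seed,
                                      alpha = hic_cfg$alpha,
                                      mean_count = hic_cfg$mean_count)
  pu_zga <- pileup(contacts, zga_pairs, hic_cfg$w, hic_cfg$nshifts,
                   hic_cfg$shift_seed)
  pu_ctrl <- tryCatch({
    ctrl_pairs <- enumerate_anchor_pairs(peaks_df, pcg_prom,
                                         hic_cfg$resolution, hic_cfg$min_sep,
                                         hic_cfg$max_sep)
    loop_key <- paste(loops$chrom, loops$bin_a, loops$bin_b)
    ctrl_pairs <- ctrl_pairs[!paste(ctrl_pairs$chrom, ctrl_pairs$bin_a,
                                    ctrl_pairs$bin_b) %in% loop_key, ]
    pileup(contacts, ctrl_pairs, hic_cfg$w, hic_cfg$nshifts,
           hic_cfg$shift_seed)
  }, error = function(e) NULL)
  genome$truth$planted_loops <- loops
  report$hic <- list(
    n_zga_pairs = pu_zga$n_pairs, zga_center_ratio = pu_zga$center_ratio,
    n_control_pairs = if (is.null(pu_ctrl)) 0L else pu_ctrl$n_pairs,
    control_center_ratio = if (is.null(pu_ctrl)) NA_real_
                           else pu_ctrl$center_ratio)

  report$three_waves <- three_wave_summary(report)

  out <- structure(list(report = report, genome = genome, domains = domains,
                        tracks = scaled, gene_sets = sets, config = config),
                   class = "run_report")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

## promoter windows of a gene-id set as a region data frame
promoter_regions <- function(genome, gene_ids, flank = 2000) {
  g <- genome$genes[genome$genes$gene_id %in% gene_ids, , drop = FALSE]
  data.frame(chrom = g$chrom,
             start = pmax(0, g$tss - flank), end = g$tss + flank,
             gene_id = g$gene_id, stringsAsFactors = FALSE)
}

## synthetic distal elements: one partner peak a few bins away from each
## promoter, within chromosome bounds
distal_partner_peaks <- function(genome, promoters, hic_cfg) {
  res <- hic_cfg$resolution
  offset <- (hic_cfg$min_sep + 3) * res
  mid <- floor((promoters$start + promoters$end) / 2)
  pos <- ifelse(mid + offset + res < genome$chromosomes[promoters$chrom],
                mid + offset, mid - offset)
  data.frame(chrom = promoters$chrom, start = pmax(0, pos - 500),
             end = pos + 500, stringsAsFactors = FALSE)
}

three_wave_summary <- function(report) {
  tb <- function(stage) {
    d <- report$domains[[stage]]
    if (is.null(d)) NA_real_ else d$total_bases
  }
  med <- function(stage) {
    d <- report$domains[[stage]]
    if (is.null(d) || !nrow(d$size)) NA_real_ else d$size$median
  }
  pat_excess <- vapply(names(report$domains), function(stage) {
    d <- report$domains[[stage]]
    d$paternal_bases / max(d$maternal_bases, 1)
  }, numeric(1))
  stages <- names(report$domains)
  list(
    total_bases = setNames(lapply(stages, tb), stages),
    median_size = setNames(lapply(stages, med), stages),
    paternal_over_maternal_bases = as.list(pat_excess),
    gv_over_mii_bases = tb("GV") / max(tb("MII"), 1),
    zygote_over_early2c_bases = tb("zygote") / max(tb("early2C"), 1))
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- result$report
  write.table(report$scale_factors, file.path(outdir, "scale_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (stage in names(result$domains)) {
    dom <- result$domains[[stage]]$combined
    dom$score <- dom$mean_signal
    write_bed(dom, file.path(outdir, paste0("domains_", stage, ".bed")),
              name_field = "stage")
  }
  write_gene_sets(result$gene_sets, file.path(outdir, "gene_sets.tsv"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$genome$truth, file.path(outdir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("Synthetic acetylation-dynamics study (seed ", r$seed, ")\n", sep = "")
  cat("Scale factors:\n")
  print(r$scale_factors, row.names = FALSE)
  cat("Domains per stage (n, median bp, total bases):\n")
  for (stage in names(r$domains)) {
    d <- r$domains[[stage]]
    cat(sprintf("  %-8s n=%4d  median=%8g  total=%10g\n", stage, d$n,
                if (nrow(d$size)) d$size$median else NA, d$total_bases))
  }
  if (!is.null(r$allelic))
    cat(sprintf("Allelic: %d/%d fragments kept; concordance %.1f%%\n",
                r$allelic$n_kept, r$allelic$n_fragments,
                r$allelic$assigned_concordance_pct))
  if (!is.null(r$hic))
    cat(sprintf("Pile-up center ratio: ZGA %.2f, control %.2f\n",
                r$hic$zga_center_ratio, r$hic$control_center_ratio))
  invisible(x)
}
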