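## Gene-class definitions from differential-expression tables. Cutoff
## conventions: fold change compared on the log2 scale against exact
## log2(cutoff); "mean FPKM cutoff" applied as max of the two group means;
## minor ZGA genes are the transcription-dependent genes, i.e. those LOWER
## in the transcription-inhibited (DRB) sample than in the control.

#' Filter a DE table by fold change, significance and expression
#'
#' Selects genes with `|log2fc| >= log2(fc_cutoff)` in the requested
#' direction (`log2fc` is condition b over a), `padj <= padj_cutoff`, and
#' `max(mean_fpkm_a, mean_fpkm_b) >= min_mean_fpkm`.
#'
#' @param table DE data frame (see [read_de_table()]).
#' @param fc_cutoff Fold-change cutoff (> 0, linear scale).
#' @param padj_cutoff Adjusted p-value cutoff (> 0).
#' @param min_mean_fpkm Expression cutoff on the larger group mean.
#' @param direction `"up"` (b over a) or `"down"`.
#' @return Sorted character vector of gene ids.
#' @export
de_filter <- function(table, fc_cutoff, padj_cutoff, min_mean_fpkm = 1,
                      direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (fc_cutoff <= 0 || padj_cutoff <= 0)
    stop("cutoffs must be positive")
  lfc <- log2(fc_cutoff)
  fc_ok <- if (direction == "up") table$log2fc >= lfc
           else table$log2fc <= -lfc
  keep <- fc_ok & table$padj <= padj_cutoff &
    pmax(table$mean_fpkm_a, table$mean_fpkm_b) >= min_mean_fpkm
  keep[is.na(keep)] <- FALSE
  sort(unique(table$gene_id[keep]))
}

gene_set <- function(name, ids, provenance) {
  structure(list(name = name, gene_ids = sort(unique(ids)),
                 provenance = provenance), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d gene(s)\n  provenance: %s\n", x$name,
              length(x$gene_ids), x$provenance))
  invisible(x)
}

#' Major ZGA genes
#'
#' Genes up-regulated from zygote to late 2-cell: fold change >= 4,
#' adjusted p <= 0.01, mean FPKM >= 1.
#'
#' @param de_late2c_vs_zygote DE table with a = zygote, b = late 2-cell.
#' @param fc_cutoff,padj_cutoff,min_mean_fpkm Cutoffs (defaults 4, 0.01, 1).
#' @return A `GeneSet`.
#' @export
define_major_zga <- function(de_late2c_vs_zygote, fc_cutoff = 4,
                             padj_cutoff = 0.01, min_mean_fpkm = 1) {
  ids <- de_filter(de_late2c_vs_zygote, fc_cutoff, padj_cutoff,
                   min_mean_fpkm, "up")
  gene_set("major_zga", ids, sprintf(
    "up in late2C vs zygote; FC>=%g, padj<=%g, meanFPKM>=%g",
    fc_cutoff, padj_cutoff, min_mean_fpkm))
}

#' Maternal decay genes
#'
#' Union of genes down-regulated versus MII oocyte in each of zygote, early
#' 2-cell, late 2-cell and 4-cell: fold change >= 4, adjusted p <= 0.01,
#' mean FPKM >= 1 per contrast.
#'
#' @param de_tables List of DE tables, each with a = MII and b = the later
#'   stage (zygote, early 2-cell, late 2-cell, 4-cell).
#' @param fc_cutoff,padj_cutoff,min_mean_fpkm Cutoffs (defaults 4, 0.01, 1).
#' @return A `GeneSet`.
#' @export
define_maternal_decay <- function(de_tables, fc_cutoff = 4,
                                  padj_cutoff = 0.01, min_mean_fpkm = 1) {
  ids <- unlist(lapply(de_tables, de_filter, fc_cutoff = fc_cutoff,
                       padj_cutoff = padj_cutoff,
                       min_mean_fpkm = min_mean_fpkm, direction = "down"))
  gene_set("maternal_decay", ids, sprintf(
    "down vs MII in any of %d contrasts; FC>=%g, padj<=%g, meanFPKM>=%g",
    length(de_tables), fc_cutoff, padj_cutoff, min_mean_fpkm))
}

#' Minor ZGA genes from a transcription-inhibition contrast
#'
#' Transcription-dependent genes at the given stage: significantly lower in
#' the DRB-treated sample than in the control (fold change >= 2, adjusted
#' p <= 0.05, mean FPKM >= 1).
#'
#' @param de_drb_vs_control DE table with a = control, b = DRB-treated.
#' @param stage `"zygote"` or `"early2C"` (names the resulting set).
#' @param fc_cutoff,padj_cutoff,min_mean_fpkm Cutoffs (defaults 2, 0.05, 1).
#' @return A `GeneSet` named `<stage>_minor_zga`.
#' @export
define_minor_zga <- function(de_drb_vs_control, stage = c("zygote", "early2C"),
                             fc_cutoff = 2, padj_cutoff = 0.05,
                             min_mean_fpkm = 1) {
  stage <- match.arg(stage)
  ids <- de_filter(de_drb_vs_control, fc_cutoff, padj_cutoff,
                   min_mean_fpkm, "down")
  name <- if (stage == "zygote") "zygote_minor_zga" else "early2c_minor_zga"
  gene_set(name, ids, sprintf(
    "down in DRB vs control at %s; FC>=%g, padj<=%g, meanFPKM>=%g",
    stage, fc_cutoff, padj_cutoff, min_mean_fpkm))
}

#' Polycomb-target genes
#'
#' Genes whose promoter carries the repressive H3K27me3 mark and whose
#' expression stays below `fpkm_max` (strictly) in every stage.
#'
#' @param promoter_h3k27me3_flags Named logical vector (gene id ->
#'   promoter marked).
#' @param expression_by_stage Numeric matrix, genes x stages (FPKM).
#' @param fpkm_max Strict upper bound on expression (default 0.1).
#' @return A `GeneSet`.
#' @export
define_pcg_targets <- function(promoter_h3k27me3_flags, expression_by_stage,
                               fpkm_max = 0.1) {
  ids <- rownames(expression_by_stage)
  marked <- names(promoter_h3k27me3_flags)[promoter_h3k27me3_flags]
  silent <- ids[apply(expression_by_stage, 1, max) < fpkm_max]
  gene_set("pcg_target", intersect(marked, silent), sprintf(
    "H3K27me3-marked promoter and FPKM < %g at every stage", fpkm_max))
}

#' Derive all five gene classes from a set of synthetic or real tables
#'
#' Convenience wrapper applying the class definitions to the table bundle
#' produced by [generate_expression_tables()].
#'
#' @param tables List with `de` (named DE tables), `expression`, and
#'   `promoter_h3k27me3` as produced by [generate_expression_tables()].
#' @return Named list of `GeneSet`s.
#' @export
derive_gene_sets <- function(tables) {
  list(
    zygote_minor_zga = define_minor_zga(tables$de$drb_zygote, "zygote"),
    early2c_minor_zga = define_minor_zga(tables$de$drb_early2c, "early2C"),
    major_zga = define_major_zga(tables$de$late2c_vs_zygote),
    maternal_decay = define_maternal_decay(tables$de[c(
      "zygote_vs_mii", "early2c_vs_mii", "late2c_vs_mii", "fourc_vs_mii")]),
    pcg_target = define_pcg_targets(tables$promoter_h3k27me3,
                                    tables$expression))
}

#' Write gene sets as a TSV with provenance
#'
#' @param sets Named list of `GeneSet`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s)
    if (length(s$gene_ids))
      data.frame(gene_id = s$gene_ids, set = s$name,
                 provenance = s$provenance, stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
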