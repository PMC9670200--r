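## Repeat-family pseudo-genome: each family becomes one pseudo-chromosome by
## concatenating its instances (genomic sort order, minus-strand instances
## reverse-complemented) with 200-N spacers between consecutive instances,
## and family-level expression is quantified by exact-substring placement of
## error-free reads (reads spanning a spacer can never match).

SPACER_LEN <- 200L

revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Build a repeat-family pseudo-genome
#'
#' @param repeat_annotations Data frame with `family`, `chrom`, `start`,
#'   `end`, `strand`; instances must lie within the genome.
#' @param genome_sequence Named character vector of chromosome sequences.
#' @return Object of class `PseudoGenome`: list with `sequences` (one string
#'   per family), `coord_map` (data frame mapping each instance to its
#'   offset in the pseudo-chromosome), and `annotation` (one gene per
#'   family: `gene_id`, `chrom` = family, `start` = 0, `end` = length).
#'   Families with no instances are omitted with a warning.
#' @export
build_pseudo_genome <- function(repeat_annotations, genome_sequence) {
  fams <- unique(repeat_annotations$family)
  sequences <- character(0)
  map_rows <- list()
  for (fam in fams) {
    inst <- repeat_annotations[repeat_annotations$family == fam, , drop = FALSE]
    if (!nrow(inst)) {
      warning("repeat family ", fam, " has no instances; omitted")
      next
    }
    key <- match(inst$chrom, unique(inst$chrom[natural_chrom_order(inst$chrom)]))
    inst <- inst[order(key, inst$start), , drop = FALSE]
    pieces <- character(nrow(inst))
    offset <- 0L
    for (i in seq_len(nrow(inst))) {
      chrom_seq <- genome_sequence[[inst$chrom[i]]]
      if (is.null(chrom_seq) || inst$end[i] > nchar(chrom_seq))
        stop("repeat instance outside genome bounds on ", inst$chrom[i])
      s <- substring(chrom_seq, inst$start[i] + 1, inst$end[i])
      if (inst$strand[i] == "-") s <- revcomp(s)
      pieces[i] <- s
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        family = fam, chrom = inst$chrom[i], start = inst$start[i],
        end = inst$end[i], strand = inst$strand[i], offset = offset,
        stringsAsFactors = FALSE)
      offset <- offset + nchar(s) + SPACER_LEN
    }
    sequences[[fam]] <- paste(pieces,
                              collapse = strrep("N", SPACER_LEN))
  }
  if (!length(sequences)) stop("no repeat family with instances")
  ann <- data.frame(gene_id = names(sequences), chrom = names(sequences),
                    start = 0, end = nchar(sequences), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(sequences = sequences,
                 coord_map = do.call(rbind, map_rows),
                 annotation = ann),
            class = "PseudoGenome")
}

#' @export
print.PseudoGenome <- function(x, ...) {
  cat(sprintf("PseudoGenome: %d famil%s, %d instance(s)\n",
              length(x$sequences),
              if (length(x$sequences) == 1) "y" else "ies",
              nrow(x$coord_map)))
  for (fam in names(x$sequences))
    cat(sprintf("  %s: %d bp (%d instances)\n", fam, nchar(x$sequences[[fam]]),
                sum(x$coord_map$family == fam)))
  invisible(x)
}

#' Map a pseudo-chromosome position back to its source base
#'
#' Inverts the pseudo-genome coordinate map: spacer positions map to `NA`;
#' instance positions map to the exact source chromosome and 0-based offset
#' (accounting for reverse-complemented minus-strand instances).
#'
#' @param pseudo_genome A [build_pseudo_genome()] result.
#' @param family Family (pseudo-chromosome) name.
#' @param pos 0-based position(s) in the pseudo-chromosome.
#' @return Data frame with `chrom`, `pos`, `strand` (`NA` rows for spacer
#'   positions).
#' @export
map_pseudo_to_source <- function(pseudo_genome, family, pos) {
  cm <- pseudo_genome$coord_map
  cm <- cm[cm$family == family, , drop = FALSE]
  if (!nrow(cm)) stop("unknown family: ", family)
  out <- data.frame(chrom = NA_character_, pos = NA_real_,
                    strand = NA_character_)[rep(1, length(pos)), ]
  rownames(out) <- NULL
  for (i in seq_len(nrow(cm))) {
    w <- cm$end[i] - cm$start[i]
    hit <- pos >= cm$offset[i] & pos < cm$offset[i] + w
    local <- pos[hit] - cm$offset[i]
    out$chrom[hit] <- cm$chrom[i]
    out$strand[hit] <- cm$strand[i]
    out$pos[hit] <- if (cm$strand[i] == "-") cm$end[i] - 1 - local
                    else cm$start[i] + local
  }
  out
}

#' Quantify repeat-family expression from error-free reads
#'
#' A read counts for a family iff it occurs as an exact substring of that
#' family's pseudo-chromosome on either strand. Reads matching k > 1
#' families are split 1/k to each; reads matching no family (including
#' reads straddling an N spacer) are tallied as `unassigned`.
#'
#' @param pseudo_genome A [build_pseudo_genome()] result.
#' @param reads Character vector of read sequences (or a data frame with a
#'   `read` column).
#' @return Named numeric vector of per-family counts, with attribute
#'   `unassigned` (count of unmatched reads).
#' @export
quantify_repeat_reads <- function(pseudo_genome, reads) {
  if (is.data.frame(reads)) reads <- reads$read
  fams <- names(pseudo_genome$sequences)
  counts <- setNames(numeric(length(fams)), fams)
  unassigned <- 0
  rc <- revcomp(reads)
  for (i in seq_along(reads)) {
    if (grepl("N", reads[i], fixed = TRUE)) {  # N never matches a base
      unassigned <- unassigned + 1
      next
    }
    hit <- vapply(fams, function(fam) {
      s <- pseudo_genome$sequences[[fam]]
      grepl(reads[i], s, fixed = TRUE) || grepl(rc[i], s, fixed = TRUE)
    }, logical(1))
    k <- sum(hit)
    if (k == 0) unassigned <- unassigned + 1
    else counts[hit] <- counts[hit] + 1 / k
  }
  attr(counts, "unassigned") <- unassigned
  counts
}

#' Write a pseudo-genome as FASTA (plus minimal GTF annotation)
#'
#' @param pseudo_genome A [build_pseudo_genome()] result.
#' @param fasta_path Output FASTA file.
#' @param gtf_path Optional output GTF treating each family as one gene.
#' @return `fasta_path`, invisibly.
#' @export
write_pseudo_genome <- function(pseudo_genome, fasta_path, gtf_path = NULL) {
  seqs <- Biostrings::DNAStringSet(pseudo_genome$sequences)
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(gtf_path)) {
    ann <- pseudo_genome$annotation
    writeLines(sprintf(
      "%s\tacetydyn\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\";",
      ann$chrom, ann$start + 1, ann$end, ann$gene_id), gtf_path)
  }
  invisible(fasta_path)
}
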