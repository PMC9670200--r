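## Readers and writers for the plain-text formats the pipeline touches.
## All internal coordinates are 0-based half-open (BED convention); GTF input
## (1-based closed) is converted on read. Chromosomes are ordered naturally
## (chr1 < chr2 < chr10).

#' Read a bedGraph file into a binned signal track
#'
#' Records are distributed over fixed-width bins by length-weighted mean, so a
#' record covering half a bin contributes half its value to that bin;
#' uncovered bins are 0. This preserves per-base FPKM semantics when records
#' do not align to the bin grid.
#'
#' @param path bedGraph file (chrom, start, end, value; tab-separated).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; required
#'   to represent chromosomes absent from the file (e.g. an empty file).
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL) {
  df <- read_table_or_empty(path, c("chrom", "start", "end", "value"),
                            c("character", "numeric", "numeric", "numeric"))
  if (any(df$value < 0))
    stop("negative value in bedGraph at line ", which(df$value < 0)[1])
  if (any(df$end <= df$start))
    stop("empty or reversed interval in bedGraph")
  chroms <- unique(df$chrom)
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(chroms, names(chrom_lengths))
    if (length(unknown))
      stop("bedGraph chromosome(s) not in chrom_lengths: ",
           paste(unknown, collapse = ", "))
    chroms <- names(chrom_lengths)
  }
  values <- list()
  for (chrom in chroms) {
    rec <- df[df$chrom == chrom, , drop = FALSE]
    rec <- rec[order(rec$start), , drop = FALSE]
    if (nrow(rec) > 1) {
      clash <- which(rec$start[-1] < rec$end[-nrow(rec)])
      if (length(clash))
        stop(sprintf("overlapping bedGraph records on %s: [%g,%g) and [%g,%g)",
                     chrom, rec$start[clash[1]], rec$end[clash[1]],
                     rec$start[clash[1] + 1], rec$end[clash[1] + 1]))
    }
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]]
           else if (nrow(rec)) max(rec$end) else 0
    nb <- ceiling(len / bin_size)
    v <- numeric(nb)
    for (i in seq_len(nrow(rec))) {
      b0 <- rec$start[i] %/% bin_size
      b1 <- (rec$end[i] - 1) %/% bin_size
      bins <- b0:b1
      lo <- pmax(bins * bin_size, rec$start[i])
      hi <- pmin((bins + 1) * bin_size, rec$end[i])
      keep <- bins < nb
      v[bins[keep] + 1L] <- v[bins[keep] + 1L] +
        rec$value[i] * (hi[keep] - lo[keep]) / bin_size
    }
    values[[chrom]] <- v
  }
  signal_track(values, bin_size, chrom_lengths = chrom_lengths)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued bins are collapsed into one record; zero-valued runs
#' are omitted (bedGraph gaps read back as 0). Records are bin-aligned, so a
#' `read_bedgraph()` round-trip at the same bin size is lossless.
#'
#' @param track A [signal_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chrom in track_chroms(track)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s", chrom, starts[keep] * bs,
                       ends[keep] * bs, format(r$values[keep], digits = 15)),
               con)
  }
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Writes BED3, or BED6 when a name column is requested (score defaults to 0,
#' strand to "."). Output is sorted by natural chromosome order then start.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output file.
#' @param name_field Optional column to use as the BED name field; selecting
#'   one switches output to BED6.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_field = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  uc <- unique(intervals$chrom)
  uc <- uc[natural_chrom_order(uc)]
  key <- match(intervals$chrom, uc)
  iv <- intervals[order(key, intervals$start, intervals$end), , drop = FALSE]
  if (is.null(name_field)) {
    lines <- sprintf("%s\t%.0f\t%.0f", iv$chrom, iv$start, iv$end)
  } else {
    name <- as.character(iv[[name_field]])
    score <- if ("score" %in% names(iv)) iv$score else 0
    strand <- if ("strand" %in% names(iv)) iv$strand else "."
    lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s", iv$chrom, iv$start,
                     iv$end, name, format(score, digits = 15), strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path BED file.
#' @return Data frame with `chrom`, `start`, `end` and, if present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  ncol <- length(strsplit(first, "\t")[[1]])
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  types <- c("character", "numeric", "numeric", "character", "numeric",
             "character")[seq_len(min(ncol, 6))]
  df <- read_table_or_empty(path, cols, types)
  if (any(df$end <= df$start)) stop("empty or reversed BED interval")
  df
}

#' Read gene annotation (BED12 or minimal GTF)
#'
#' BED12 blocks become exons. Minimal GTF support: `gene` and `exon` features
#' with a `gene_id "..."` attribute; 1-based closed GTF coordinates are
#' converted to 0-based half-open on read. TSS/TES are strand-aware.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`, `cgi` (logical, `NA` unless encoded in the BED
#'   score as 0/1), and list-columns `exon_starts`, `exon_ends`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed12"
  if (format == "bed12") {
    df <- read_table_or_empty(path,
      c("chrom", "start", "end", "name", "score", "strand", "thick_start",
        "thick_end", "rgb", "block_count", "block_sizes", "block_starts"),
      c("character", "numeric", "numeric", "character", "numeric", "character",
        "numeric", "numeric", "character", "integer", "character", "character"))
    exon_starts <- exon_ends <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      sizes <- as.numeric(strsplit(df$block_sizes[i], ",")[[1]])
      offs <- as.numeric(strsplit(df$block_starts[i], ",")[[1]])
      exon_starts[[i]] <- df$start[i] + offs
      exon_ends[[i]] <- df$start[i] + offs + sizes
    }
    genes <- data.frame(gene_id = df$name, chrom = df$chrom, start = df$start,
                        end = df$end, strand = df$strand,
                        stringsAsFactors = FALSE)
    genes$cgi <- ifelse(df$score %in% c(0, 1), df$score == 1, NA)
  } else {
    raw <- read_table_or_empty(path,
      c("chrom", "source", "feature", "start", "end", "score", "strand",
        "frame", "attributes"),
      c("character", "character", "character", "numeric", "numeric",
        "character", "character", "character", "character"))
    raw$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", raw$attributes)
    raw$start <- raw$start - 1  # GTF is 1-based closed
    g <- raw[raw$feature == "gene", , drop = FALSE]
    e <- raw[raw$feature == "exon", , drop = FALSE]
    genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                        end = g$end, strand = g$strand,
                        stringsAsFactors = FALSE)
    genes$cgi <- NA
    exon_starts <- lapply(genes$gene_id, function(id)
      sort(e$start[e$gene_id == id]))
    exon_ends <- lapply(genes$gene_id, function(id) sort(e$end[e$gene_id == id]))
    no_exon <- lengths(exon_starts) == 0
    exon_starts[no_exon] <- lapply(which(no_exon), function(i) genes$start[i])
    exon_ends[no_exon] <- lapply(which(no_exon), function(i) genes$end[i])
  }
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tes <- ifelse(genes$strand == "-", genes$start, genes$end)
  genes$exon_starts <- exon_starts
  genes$exon_ends <- exon_ends
  genes
}

#' Write gene annotation as BED12
#'
#' Inverse of [read_gene_annotation()] for the BED12 dialect; the CGI flag is
#' stored in the score column (1 = CGI promoter, 0 = not, -1 = unknown).
#'
#' @param genes Gene table as returned by [read_gene_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    score <- if (is.na(genes$cgi[i])) -1 else as.integer(genes$cgi[i])
    sprintf("%s\t%.0f\t%.0f\t%s\t%d\t%s\t%.0f\t%.0f\t0\t%d\t%s\t%s",
            genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i],
            score, genes$strand[i], genes$start[i], genes$end[i],
            length(es), paste(ee - es, collapse = ","),
            paste(es - genes$start[i], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP table
#'
#' Tab-separated with header: `chrom`, `pos` (0-based), `maternal_base`,
#' `paternal_base`. The two bases must differ at every SNP.
#'
#' @param path TSV file.
#' @return Data frame of SNPs sorted by chromosome and position.
#' @export
read_snp_table <- function(path) {
  df <- read_table_or_empty(path,
    c("chrom", "pos", "maternal_base", "paternal_base"),
    c("character", "numeric", "character", "character"), header = TRUE)
  if (any(df$maternal_base == df$paternal_base))
    stop("SNP with identical maternal and paternal base")
  key <- match(df$chrom, unique(df$chrom[natural_chrom_order(df$chrom)]))
  df[order(key, df$pos), , drop = FALSE]
}

#' @rdname read_snp_table
#' @param snps SNP data frame.
#' @export
write_snp_table <- function(snps, path) {
  write.table(snps[, c("chrom", "pos", "maternal_base", "paternal_base")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Tab-separated with header: `gene_id`, `mean_fpkm_a`, `mean_fpkm_b`,
#' `log2fc` (condition b over a), `padj`.
#'
#' @param path TSV file.
#' @return Data frame with those columns.
#' @export
read_de_table <- function(path) {
  df <- read_table_or_empty(path,
    c("gene_id", "mean_fpkm_a", "mean_fpkm_b", "log2fc", "padj"),
    c("character", "numeric", "numeric", "numeric", "numeric"), header = TRUE)
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  if (any(df$mean_fpkm_a < 0 | df$mean_fpkm_b < 0))
    stop("negative FPKM")
  df
}

#' @rdname read_de_table
#' @param de DE data frame.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("gene_id", "mean_fpkm_a", "mean_fpkm_b", "log2fc", "padj")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragment records from extended BED
#'
#' Columns: `chrom`, `start`, `end`, `id`, `mapq`, `duplicate` (0/1), `snps`
#' (semicolon-separated `pos:base` pairs, or `.`). Every SNP call position
#' must lie within the fragment interval.
#'
#' @param path Extended-BED file.
#' @return Data frame of fragments with a list-column `snp_calls` of
#'   `(pos, base)` data frames.
#' @export
read_fragments <- function(path) {
  df <- read_table_or_empty(path,
    c("chrom", "start", "end", "id", "mapq", "duplicate", "snps"),
    c("character", "numeric", "numeric", "character", "numeric", "integer",
      "character"))
  df$duplicate <- df$duplicate == 1L
  df$snp_calls <- lapply(seq_len(nrow(df)), function(i) {
    parse_snp_calls(df$snps[i], df$start[i], df$end[i])
  })
  df$snps <- NULL
  df
}

parse_snp_calls <- function(s, start, end) {
  if (is.na(s) || s == "." || s == "")
    return(data.frame(pos = numeric(), base = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  pos <- as.numeric(vapply(parts, `[`, "", 1))
  base <- vapply(parts, `[`, "", 2)
  if (any(pos < start | pos >= end))
    stop("SNP call outside fragment interval")
  data.frame(pos = pos, base = base, stringsAsFactors = FALSE)
}

#' @rdname read_fragments
#' @param fragments Fragment data frame (with `snp_calls` list-column).
#' @export
write_fragments <- function(fragments, path) {
  snps <- vapply(fragments$snp_calls, function(sc) {
    if (!nrow(sc)) "." else paste(sprintf("%.0f:%s", sc$pos, sc$base),
                                  collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%g\t%d\t%s", fragments$chrom,
                   fragments$start, fragments$end, fragments$id,
                   fragments$mapq, as.integer(fragments$duplicate), snps)
  writeLines(lines, path)
  invisible(path)
}

#' Read a Hi-C contact matrix from bin-pair triplet text
#'
#' Lines are `chrom bin_i bin_j count` with `bin_i <= bin_j` (or three
#' columns for a single unnamed chromosome). The matrix is stored dense and
#' symmetric; duplicate bin pairs are an error rather than being summed.
#'
#' @param path Triplet text file.
#' @param resolution Bin width in bp.
#' @param n_bins Optional named vector giving the bin count per chromosome;
#'   inferred from the largest bin index otherwise.
#' @return An object of class `ContactMatrix`: list with `resolution` and
#'   `matrices` (chromosome-named list of symmetric matrices).
#' @export
read_contacts <- function(path, resolution, n_bins = NULL) {
  first <- readLines(path, n = 1L)
  four <- length(first) && length(strsplit(first, "\t")[[1]]) == 4
  if (four) {
    df <- read_table_or_empty(path, c("chrom", "bin_i", "bin_j", "count"),
      c("character", "integer", "integer", "numeric"))
  } else {
    df <- read_table_or_empty(path, c("bin_i", "bin_j", "count"),
      c("integer", "integer", "numeric"))
    df$chrom <- "chr1"
  }
  if (any(df$count < 0)) stop("negative contact count")
  if (any(df$bin_i > df$bin_j)) stop("triplet with bin_i > bin_j")
  matrices <- list()
  chroms <- if (!is.null(n_bins)) names(n_bins) else unique(df$chrom)
  for (chrom in chroms) {
    rec <- df[df$chrom == chrom, , drop = FALSE]
    nb <- if (!is.null(n_bins)) n_bins[[chrom]]
          else if (nrow(rec)) max(rec$bin_j) + 1L else 0L
    if (nrow(rec) && max(rec$bin_j) >= nb)
      stop("bin index out of range on ", chrom)
    if (anyDuplicated(rec[, c("bin_i", "bin_j")]))
      stop("duplicate bin pair on ", chrom, " (no silent summing)")
    m <- matrix(0, nb, nb)
    m[cbind(rec$bin_i + 1L, rec$bin_j + 1L)] <- rec$count
    m[cbind(rec$bin_j + 1L, rec$bin_i + 1L)] <- rec$count
    matrices[[chrom]] <- m
  }
  contact_matrix(matrices, resolution)
}

#' Construct a ContactMatrix from per-chromosome matrices
#'
#' @param matrices Chromosome-named list of symmetric square matrices.
#' @param resolution Bin width in bp.
#' @return A `ContactMatrix`.
#' @export
contact_matrix <- function(matrices, resolution) {
  for (chrom in names(matrices)) {
    m <- matrices[[chrom]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("contact matrix on ", chrom, " is not square")
    if (any(m < 0)) stop("negative contact count on ", chrom)
    if (!isTRUE(all.equal(m, t(m)))) stop("asymmetric contacts on ", chrom)
  }
  structure(list(matrices = matrices, resolution = as.integer(resolution)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d chromosome(s) at %d bp resolution\n",
              length(x$matrices), x$resolution))
  for (chrom in names(x$matrices))
    cat(sprintf("  %s: %d bins, total count %g\n", chrom,
                nrow(x$matrices[[chrom]]), sum(x$matrices[[chrom]])))
  invisible(x)
}

#' @rdname read_contacts
#' @param contacts A `ContactMatrix`.
#' @export
write_contacts <- function(contacts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(contacts$matrices)) {
    m <- contacts$matrices[[chrom]]
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, idx[, 1] - 1L,
                         idx[, 2] - 1L, m[idx]), con)
  }
  invisible(path)
}

## shared low-level table reader tolerant of empty files
read_table_or_empty <- function(path, col_names, col_classes, header = FALSE) {
  empty <- function() {
    df <- as.data.frame(setNames(
      lapply(col_classes, function(cl) vector(cl, 0L)), col_names),
      stringsAsFactors = FALSE)
    df
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(empty())
  df <- read.table(path, sep = "\t", header = header,
                   col.names = col_names, colClasses = col_classes,
                   stringsAsFactors = FALSE, comment.char = "#",
                   quote = "")
  df
}
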