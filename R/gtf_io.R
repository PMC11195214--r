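#' Load a GTF annotation into a feature set
#'
#' Reads a GENCODE-dialect GTF (only \code{exon} records are required; they
#' must carry \code{gene_id} and \code{transcript_id} attributes), converts
#' the 1-based closed GTF coordinates to the package's 0-based half-open
#' convention, groups exons into transcripts and genes, and derives introns
#' and auxiliary regions.
#'
#' @param path GTF file.
#' @param repeats optional BED6 file of repeat intervals (name column =
#'   repeat family).
#' @param enhancers optional BED6 file of enhancer intervals.
#' @param prompt_length,readthrough_length see \code{\link{feature_set}}.
#' @return a \code{\link{feature_set}}.
#' @export
load_annotation <- function(path, repeats = NULL, enhancers = NULL,
                            prompt_length = 4000L,
                            readthrough_length = 10000L) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type == "exon"
  if (!any(keep)) stop("no exon records in ", path)
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id)) {
    stop("exon records must carry gene_id and transcript_id")
  }
  ex <- data.table(gene_id = as.character(md$gene_id),
                   tx_id = as.character(md$transcript_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr))
  rep_dt <- if (!is.null(repeats)) read_bed(repeats) else NULL
  enh_dt <- if (!is.null(enhancers)) read_bed(enhancers) else NULL
  feature_set(ex, repeats = rep_dt, enhancers = enh_dt,
              prompt_length = prompt_length,
              readthrough_length = readthrough_length)
}

# cheap structural check so malformed lines are reported by number,
# which rtracklayer's parser does not do
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[data_lines], "\t", fixed = TRUE))
  bad <- data_lines[nf < 9L]
  if (length(bad) > 0L) {
    stop("malformed GTF line ", bad[1L], " in ", path,
         " (expected 9 tab-separated fields, got ", nf[match(bad[1L], data_lines)], ")")
  }
  invisible(TRUE)
}

#' Write a feature set's gene models back to GTF
#'
#' Emits gene, transcript and exon records with \code{gene_id} and
#' \code{transcript_id} attributes. Round-trips through
#' \code{\link{load_annotation}} to identical intervals.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param path output GTF path.
#' @export
write_annotation <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  mk <- function(dt, type, tx) {
    GenomicRanges::GRanges(
      seqnames = dt$chrom,
      ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
      strand = dt$strand,
      type = type,
      source = "rnachase",
      gene_id = dt$gene_id,
      transcript_id = tx)
  }
  g <- mk(fs$genes, "gene", NA_character_)
  t <- mk(fs$transcripts, "transcript", fs$transcripts$tx_id)
  e <- mk(fs$exons, "exon", fs$exons$tx_id)
  gr <- c(g, t, e)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a BED6 file as an interval table
#'
#' Coordinates stay in BED's native 0-based half-open convention. The BED
#' name column is exposed as \code{family} (repeat files label intervals
#' with their repeat family).
#'
#' @param path BED file.
#' @return data.table(family, chrom, strand, start, end).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "+"
  data.table(family = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = st,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Summarize a feature set as a TSV
#'
#' One row per gene with transcript/exon/intron tallies and derived-region
#' coordinates; useful as a manifest of what the annotation contained.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param path output TSV path.
#' @export
write_feature_summary <- function(fs, path) {
  ic <- if (nrow(fs$introns)) fs$introns[, .(n_introns = .N), by = gene_id] else
    data.table(gene_id = character(), n_introns = integer())
  s <- merge(fs$genes, ic, by = "gene_id", all.x = TRUE)
  s[is.na(n_introns), n_introns := 0L]
  setorder(s, gene_id)
  write_tsv(s, path)
}
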