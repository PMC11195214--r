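#' Build a feature set from an exon table
#'
#' The feature set is the coordinate backbone of the pipeline: genes,
#' transcripts, exons, derived introns, per-gene union-exon space, and the
#' derived auxiliary regions used for RNA-class accounting (antisense
#' promoter-upstream windows, "PROMPTs", and sense readthrough windows past
#' the annotated 3' end). All coordinates are 0-based half-open.
#'
#' Intron \code{i} of a transcript is the gap between consecutive exons, so
#' \code{intron[i].start == exon[i].end} and
#' \code{intron[i].end == exon[i+1].start} in genomic order. Exon and intron
#' ranks are strand-aware (rank 1 is 5'-most). A base is "exonic" for a gene
#' if it is exonic in any of its transcripts (union-exon rule).
#'
#' @param exons data.table/data.frame with columns \code{gene_id},
#'   \code{tx_id}, \code{chrom}, \code{strand}, \code{start}, \code{end}
#'   (0-based half-open).
#' @param repeats optional interval table with a \code{family} column.
#' @param enhancers optional interval table of enhancer regions.
#' @param prompt_length bases of the antisense upstream window (default
#'   4000; PROMPTs are bounded at <4 kb).
#' @param readthrough_length bases of the sense window past the gene end
#'   (default 10000), clipped at the nearest same-strand downstream gene.
#' @return object of class \code{feature_set}: a list of data.tables
#'   (\code{genes}, \code{transcripts}, \code{exons}, \code{introns},
#'   \code{union_exons}, \code{prompts}, \code{readthrough},
#'   \code{repeats}, \code{enhancers}).
#' @export
feature_set <- function(exons, repeats = NULL, enhancers = NULL,
                        prompt_length = 4000L, readthrough_length = 10000L) {
  ex <- as.data.table(exons)
  req <- c("gene_id", "tx_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(ex))) {
    stop("exon table needs columns: ", paste(req, collapse = ", "))
  }
  ex <- ex[, req, with = FALSE]
  ex[, `:=`(start = as.integer(start), end = as.integer(end))]
  .check_intervals(ex, "exon")
  setorder(ex, tx_id, start)

  # overlapping exons within one transcript are malformed annotation
  bad <- ex[, any(start[-1L] < end[-.N]), by = tx_id][V1 == TRUE]
  if (nrow(bad) > 0L) {
    stop("transcript(s) with overlapping exons: ",
         paste(head(bad$tx_id, 5L), collapse = ", "))
  }
  if (nrow(unique(ex[, .(tx_id, gene_id)]))
      != length(unique(ex$tx_id)) ||
      nrow(unique(ex[, .(tx_id, strand)])) != length(unique(ex$tx_id))) {
    stop("each tx_id must map to a single gene_id and strand")
  }

  ex[, exon_rank := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = tx_id]

  introns <- ex[, {
    if (.N > 1L) {
      list(chrom = chrom[1L], strand = strand[1L], gene_id = gene_id[1L],
           start = end[-.N], end = start[-1L])
    } else {
      list(chrom = character(), strand = character(), gene_id = character(),
           start = integer(), end = integer())
    }
  }, by = tx_id]
  if (nrow(introns) > 0L) {
    introns[, intron_rank := if (strand[1L] == "+") seq_len(.N)
            else rev(seq_len(.N)), by = tx_id]
    introns[, intron_id := paste0(tx_id, ".I", intron_rank)]
  } else {
    introns[, `:=`(intron_rank = integer(), intron_id = character())]
  }

  transcripts <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                        strand = strand[1L], start = min(start),
                        end = max(end), n_exons = .N), by = tx_id]
  genes <- transcripts[, .(chrom = chrom[1L], strand = strand[1L],
                           start = min(start), end = max(end),
                           n_tx = .N), by = gene_id]

  union_exons <- .reduce_by_gene(ex)

  prompts <- derive_prompts(genes, prompt_length)
  readthrough <- derive_readthroughs(genes, readthrough_length)

  fs <- list(genes = genes, transcripts = transcripts, exons = ex,
             introns = introns, union_exons = union_exons,
             prompts = prompts, readthrough = readthrough,
             repeats = if (!is.null(repeats)) as.data.table(repeats) else NULL,
             enhancers = if (!is.null(enhancers)) as.data.table(enhancers) else NULL,
             prompt_length = as.integer(prompt_length),
             readthrough_length = as.integer(readthrough_length))
  class(fs) <- "feature_set"
  fs
}

# merge overlapping exon intervals per gene (union-exon space)
.reduce_by_gene <- function(ex) {
  u <- unique(ex[, .(gene_id, chrom, strand, start, end)])
  setorder(u, gene_id, start, end)
  u[, grp := cumsum(c(1L, as.integer(start[-1L] > cummax(end[-.N])))),
    by = gene_id]
  u[, .(chrom = chrom[1L], strand = strand[1L], start = min(start),
        end = max(end)), by = .(gene_id, grp)][, grp := NULL][]
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d genes, %d transcripts, %d exons, %d introns\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              nrow(x$introns)))
  if (!is.null(x$repeats)) cat(sprintf("  repeats: %d intervals\n", nrow(x$repeats)))
  if (!is.null(x$enhancers)) cat(sprintf("  enhancers: %d intervals\n", nrow(x$enhancers)))
  invisible(x)
}

#' Antisense promoter-upstream (PROMPT) windows
#'
#' A window of \code{length} bases immediately upstream of each gene's TSS
#' on the opposite strand, emulating promoter upstream transcripts, which
#' are short (<4 kb) divergent RNAs. Windows hitting the chromosome start
#' are truncated with a warning.
#'
#' @param genes gene table of a \code{\link{feature_set}} (or the
#'   feature_set itself).
#' @param length window size in bases (default 4000).
#' @return data.table(gene_id, chrom, strand, start, end).
#' @export
derive_prompts <- function(genes, length = 4000L) {
  g <- if (inherits(genes, "feature_set")) genes$genes else as.data.table(genes)
  length <- as.integer(length)
  plus <- g$strand == "+"
  out <- data.table(
    gene_id = g$gene_id, chrom = g$chrom,
    strand = ifelse(plus, "-", "+"),
    start = ifelse(plus, g$start - length, g$end),
    end = ifelse(plus, g$start, g$end + length))
  if (any(out$start < 0L)) {
    warning("PROMPT window truncated at chromosome start for ",
            sum(out$start < 0L), " gene(s)")
    out[start < 0L, start := 0L]
  }
  out <- out[end > start]
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  out[]
}

#' Sense readthrough windows past the annotated gene end
#'
#' A fixed-length window downstream of each gene's 3' end on the sense
#' strand, as a configurable proxy for intergenic readthrough segments.
#' The window is clipped at the nearest downstream gene on the same strand
#' (readthrough RNA entering another gene body cannot be attributed).
#'
#' @inheritParams derive_prompts
#' @param length window size in bases (default 10000).
#' @return data.table(gene_id, chrom, strand, start, end); genes whose
#'   window is fully clipped are dropped.
#' @export
derive_readthroughs <- function(genes, length = 10000L) {
  g <- if (inherits(genes, "feature_set")) genes$genes else as.data.table(genes)
  length <- as.integer(length)
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i]
    same <- g[chrom == gi$chrom & strand == gi$strand & gene_id != gi$gene_id]
    if (gi$strand == "+") {
      s <- gi$end
      e <- gi$end + length
      nxt <- same[start >= gi$end, suppressWarnings(min(start))]
      if (is.finite(nxt)) e <- min(e, nxt)
    } else {
      e <- gi$start
      s <- max(gi$start - length, 0L)
      prv <- same[end <= gi$start, suppressWarnings(max(end))]
      if (is.finite(prv)) s <- max(s, prv)
    }
    if (e > s) {
      out[[i]] <- data.table(gene_id = gi$gene_id, chrom = gi$chrom,
                             strand = gi$strand, start = as.integer(s),
                             end = as.integer(e))
    }
  }
  rbindlist(out)
}

#' Select multi-intron genes with a single annotated isoform
#'
#' Splicing-index and splicing-pattern analyses are restricted to genes
#' producing one annotated isoform with at least \code{min_introns} introns,
#' so junction evidence is unambiguous.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param min_introns minimum intron count (default 2).
#' @return character vector of gene ids.
#' @export
select_single_isoform_multi_intron <- function(fs, min_introns = 2L) {
  stopifnot(inherits(fs, "feature_set"))
  single <- fs$genes[n_tx == 1L, gene_id]
  tx <- fs$transcripts[gene_id %in% single & n_exons >= min_introns + 1L]
  sort(unique(tx$gene_id))
}
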