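# RNA-class accounting: every uniquely mapping fragment is assigned to one
# of {exon, intron, exon_antisense, intron_antisense, intergenic,
# ambiguous}. A fragment touching >= 2 distinct genes on its own strand is
# ambiguous; within a single gene, any overlap with union-exon space makes
# it exonic (the fractional coverage counter, in contrast, splits mass per
# base — two deliberately different procedures).

.RNA_CLASSES <- c("exon", "intron", "exon_antisense", "intron_antisense",
                  "intergenic", "ambiguous")

#' Classify fragments into RNA classes
#'
#' @param fset a \code{\link{fragment_set}}.
#' @param fs a \code{\link{feature_set}}.
#' @param mapq_min minimum mapping quality; 255 is the unique-mapper
#'   convention of STAR-style aligners. Fragments below it are excluded and
#'   tallied in attribute \code{"mapq_excluded"}.
#' @return data.table(frag_id, name, class) for retained fragments, class
#'   one of exon, intron, exon_antisense, intron_antisense, intergenic,
#'   ambiguous.
#' @export
classify_fragments <- function(fset, fs, mapq_min = 255L) {
  stopifnot(inherits(fset, "fragment_set"), inherits(fs, "feature_set"))
  keep <- fset$frags[mapq >= mapq_min]
  excluded <- nrow(fset$frags) - nrow(keep)
  blocks <- fset$blocks[frag_id %in% keep$frag_id]
  blocks <- merge(blocks, keep[, .(frag_id, chrom, strand)], by = "frag_id")

  res <- data.table(frag_id = keep$frag_id, name = keep$name,
                    class = "intergenic")

  if (nrow(blocks) > 0L && nrow(fs$genes) > 0L) {
    hits <- interval_overlaps(blocks, fs$genes)
    if (nrow(hits) > 0L) {
      hits <- data.table(frag_id = blocks$frag_id[hits$qid],
                         fstrand = blocks$strand[hits$qid],
                         gene_id = fs$genes$gene_id[hits$sid],
                         gstrand = fs$genes$strand[hits$sid])
      hits <- unique(hits)
      hits[, sense := fstrand == gstrand]
      per <- hits[, .(n_sense = sum(sense), n_anti = sum(!sense),
                      sense_gene = if (any(sense)) gene_id[sense][1L] else NA_character_),
                  by = frag_id]

      # exon overlap per (fragment, gene) on union-exon space
      ue_hits <- interval_overlaps(blocks, fs$union_exons)
      exonic_pairs <- unique(data.table(
        frag_id = blocks$frag_id[ue_hits$qid],
        gene_id = fs$union_exons$gene_id[ue_hits$sid]))
      exonic_pairs[, exonic := TRUE]

      # sense, single gene
      sg <- per[n_sense == 1L]
      sg <- merge(sg, exonic_pairs, by.x = c("frag_id", "sense_gene"),
                  by.y = c("frag_id", "gene_id"), all.x = TRUE)
      res[sg[is.na(exonic)], on = "frag_id", class := "intron"]
      res[sg[exonic == TRUE], on = "frag_id", class := "exon"]
      # sense, multiple genes
      res[per[n_sense >= 2L], on = "frag_id", class := "ambiguous"]
      # antisense only
      anti <- per[n_sense == 0L & n_anti >= 1L]
      if (nrow(anti) > 0L) {
        anti_genes <- hits[sense == FALSE & frag_id %in% anti$frag_id,
                           .(frag_id, gene_id)]
        anti_ex <- merge(anti_genes, exonic_pairs,
                         by = c("frag_id", "gene_id"), all.x = TRUE)
        anti_cls <- anti_ex[, .(ex = any(exonic, na.rm = TRUE)), by = frag_id]
        res[anti_cls[ex == TRUE], on = "frag_id", class := "exon_antisense"]
        res[anti_cls[ex == FALSE], on = "frag_id", class := "intron_antisense"]
      }
    }
  }
  attr(res, "mapq_excluded") <- excluded
  res[]
}

#' Per-sample RNA class profile
#'
#' Counts and fractions of the six RNA classes among retained (unique)
#' fragments; the class fractions of a sample sum to 1.
#'
#' @inheritParams classify_fragments
#' @return data.table(class, count, fraction).
#' @export
class_profile <- function(fset, fs, mapq_min = 255L) {
  cls <- classify_fragments(fset, fs, mapq_min = mapq_min)
  if (nrow(cls) == 0L) {
    stop("empty sample: no fragments at mapq >= ", mapq_min)
  }
  tab <- cls[, .(count = .N), by = class]
  out <- data.table(class = .RNA_CLASSES)
  out <- merge(out, tab, by = "class", all.x = TRUE, sort = FALSE)
  out[is.na(count), count := 0L]
  out[, fraction := count / sum(count)]
  out[]
}

#' Strand-specific fractional feature counts
#'
#' Each fragment contributes (aligned bases inside the feature on the same
#' strand) / (total aligned bases of the fragment) to a feature, and these
#' fractional contributions are summed over fragments. Over any partition
#' of the genome the contributions of one fragment sum to exactly 1, so
#' total fractional mass equals the retained fragment count.
#'
#' @param fset a \code{\link{fragment_set}}.
#' @param features interval table with columns \code{feature_id},
#'   \code{chrom}, \code{strand}, \code{start}, \code{end}; a feature may
#'   span several rows (e.g. union exons of a gene), which must not overlap
#'   each other.
#' @param mapq_min minimum mapping quality (default 255).
#' @return data.table(feature_id, count) including zero-count features.
#' @export
fractional_counts <- function(fset, features, mapq_min = 255L) {
  stopifnot(inherits(fset, "fragment_set"))
  features <- as.data.table(features)
  stopifnot(all(c("feature_id", "chrom", "strand", "start", "end")
                %in% names(features)))
  keep <- fset$frags[mapq >= mapq_min]
  blocks <- fset$blocks[frag_id %in% keep$frag_id]
  blocks <- merge(blocks, keep[, .(frag_id, chrom, strand)], by = "frag_id")
  tot <- blocks[, .(tot = sum(end - start)), by = frag_id]

  hits <- interval_overlaps(blocks, features)
  out <- data.table(feature_id = unique(features$feature_id), count = 0)
  if (nrow(hits) > 0L) {
    hh <- data.table(frag_id = blocks$frag_id[hits$qid],
                     fstrand = blocks$strand[hits$qid],
                     feature_id = features$feature_id[hits$sid],
                     sstrand = features$strand[hits$sid],
                     ov = hits$ov_end - hits$ov_start)
    hh <- hh[fstrand == sstrand]
    if (nrow(hh) > 0L) {
      hh <- merge(hh, tot, by = "frag_id")
      counts <- hh[, .(inside = sum(ov)), by = .(frag_id, feature_id, tot)][
        , .(count = sum(inside / tot)), by = feature_id]
      out[counts, on = "feature_id", count := i.count]
    }
  }
  out[]
}

#' Fractional counting of repeat-family hits including multimappers
#'
#' A fragment reported against n distinct repeat families contributes 1/n
#' to each family (RepEnrich-style fractional counting); unique hits
#' contribute 1.
#'
#' @param hits data.table(frag_id, family), one row per reported alignment
#'   (e.g. from \code{\link{sim_repeat_hits}}).
#' @return data.table(family, count).
#' @export
repeat_fractional_counts <- function(hits) {
  hits <- unique(as.data.table(hits)[, .(frag_id, family)])
  if (nrow(hits) == 0L) return(data.table(family = character(), count = numeric()))
  hits[, n_fam := .N, by = frag_id]
  out <- hits[, .(count = sum(1 / n_fam)), by = family]
  setorder(out, family)
  out[]
}

#' Relative stability of an RNA class versus exons
#'
#' The fold change of a class's read fraction between 0h and a chase
#' timepoint, normalized to the fold change of the exon class:
#' \deqn{(f_{class}(t)/f_{class}(0)) / (f_{exon}(t)/f_{exon}(0)).}
#' Values below 1 mean the class turns over faster than protein-coding
#' exonic RNA; exon versus itself is 1 by construction.
#'
#' @param profile_0h,profile_t class profiles from
#'   \code{\link{class_profile}}.
#' @param class class name to compare (e.g. "intron").
#' @return numeric fold value, NA when a required fraction is zero.
#' @export
relative_class_stability <- function(profile_0h, profile_t, class) {
  cls <- as.character(class)
  grab <- function(prof, what) prof$fraction[prof$class == what]
  f0c <- grab(profile_0h, cls)
  ftc <- grab(profile_t, cls)
  f0e <- grab(profile_0h, "exon")
  fte <- grab(profile_t, "exon")
  if (length(f0c) != 1L || length(f0e) != 1L) stop("unknown class: ", class)
  if (f0c == 0 || f0e == 0 || fte == 0) return(NA_real_)
  (ftc / f0c) / (fte / f0e)
}

#' Exonic count matrix across samples
#'
#' Fractional counts over per-gene union-exon space, one column per sample,
#' with gene lengths (union-exon bases) for RPKM filtering downstream.
#'
#' @param fsets named list of \code{\link{fragment_set}} objects.
#' @param fs a \code{\link{feature_set}}.
#' @param sample_sheet data.table with columns \code{sample},
#'   \code{cell_line}, \code{timepoint}, \code{replicate}; rows must match
#'   \code{names(fsets)}.
#' @param mapq_min minimum mapping quality.
#' @return object of class \code{count_matrix}: list(counts = gene x
#'   sample matrix, samples = metadata, lengths = named union-exon bases).
#' @export
exonic_count_matrix <- function(fsets, fs, sample_sheet, mapq_min = 255L) {
  sheet <- as.data.table(sample_sheet)
  stopifnot(all(sheet$sample %in% names(fsets)))
  feats <- fs$union_exons[, .(feature_id = gene_id, chrom, strand, start, end)]
  lens <- fs$union_exons[, .(len = sum(end - start)), by = gene_id]
  genes <- sort(lens$gene_id)
  counts <- matrix(0, nrow = length(genes), ncol = nrow(sheet),
                   dimnames = list(genes, sheet$sample))
  for (i in seq_len(nrow(sheet))) {
    fc <- fractional_counts(fsets[[sheet$sample[i]]], feats,
                            mapq_min = mapq_min)
    counts[, i] <- fc[match(genes, feature_id), count]
  }
  structure(list(counts = counts, samples = sheet,
                 lengths = setNames(lens$len, lens$gene_id)[genes]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$timepoint), collapse = "/")))
  invisible(x)
}
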