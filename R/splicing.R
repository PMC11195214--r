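# Intron-centric splicing quantification from junction-informative
# fragments. For an intron, a = split fragments (exon->exon), b = fragments
# contiguously crossing the 5' exon-intron boundary, c = fragments crossing
# the 3' intron-exon boundary, each with a minimum aligned overlap on both
# sides of the junction (default 10 nt). jrsum = a + b + c and
# SI = a / (a + (b + c) / 2), so SI is the fraction of junction evidence
# that is spliced, in [0, 1]. A fragment contiguously covering an entire
# retained intron evidences both unspliced junctions and counts once
# toward b and once toward c.

# introns eligible for junction counting: single-isoform, multi-intron genes
.eligible_introns <- function(fs, min_introns = 2L) {
  genes <- select_single_isoform_multi_intron(fs, min_introns = min_introns)
  fs$introns[gene_id %in% genes]
}

#' Junction events per (fragment, intron)
#'
#' Classifies every fragment against every eligible intron on the same
#' strand: type "a" when a within-mate block pair spans exactly the intron
#' (left block ends at intron start, right block begins at intron end) with
#' at least \code{min_overlap} aligned bases on both flanks; "b"/"c" when a
#' contiguous block crosses the intron start/end with \code{min_overlap}
#' bases on each side. Events are deduplicated per (fragment, intron, type).
#'
#' @param fset a \code{\link{fragment_set}}.
#' @param fs a \code{\link{feature_set}}.
#' @param introns optionally, an intron table (defaults to introns of
#'   single-isoform multi-intron genes).
#' @param min_overlap minimum aligned bases on each side of a junction
#'   (default 10).
#' @param mapq_min minimum mapping quality.
#' @return data.table(frag_id, intron_id, type) with type in {a, b, c}.
#' @export
junction_events <- function(fset, fs, introns = NULL, min_overlap = 10L,
                            mapq_min = 255L) {
  stopifnot(inherits(fset, "fragment_set"))
  if (is.null(introns)) introns <- .eligible_introns(fs)
  introns <- as.data.table(introns)
  keep <- fset$frags[mapq >= mapq_min]
  blocks <- fset$blocks[frag_id %in% keep$frag_id]
  blocks <- merge(blocks, keep[, .(frag_id, chrom, strand)], by = "frag_id")
  if (nrow(blocks) == 0L || nrow(introns) == 0L) {
    return(data.table(frag_id = integer(), intron_id = character(),
                      type = character()))
  }
  setorder(blocks, frag_id, mate, start)

  # split events: within-mate adjacent block pairs matching an intron
  gaps <- blocks[, if (.N > 1L) .(
    gstart = end[-.N], gend = start[-1L],
    left_w = (end - start)[-.N], right_w = (end - start)[-1L],
    chrom = chrom[1L], strand = strand[1L]),
    by = .(frag_id, mate)]
  a_ev <- if (nrow(gaps) > 0L) {
    merge(gaps[left_w >= min_overlap & right_w >= min_overlap],
          introns[, .(intron_id, chrom, strand, gstart = start, gend = end)],
          by = c("chrom", "strand", "gstart", "gend"))[
            , .(frag_id, intron_id, type = "a")]
  } else data.table(frag_id = integer(), intron_id = character(),
                    type = character())

  # contiguous crossings of one boundary point p: block [p - ov, p + ov]
  cross_events <- function(points, type) {
    pts <- data.table(chrom = points$chrom, strand = points$strand,
                      intron_id = points$intron_id,
                      start = points$p - min_overlap,
                      end = points$p + min_overlap)
    hits <- interval_overlaps(blocks, pts)
    if (nrow(hits) == 0L) {
      return(data.table(frag_id = integer(), intron_id = character(),
                        type = character()))
    }
    ok <- blocks$start[hits$qid] <= pts$start[hits$sid] &
      blocks$end[hits$qid] >= pts$end[hits$sid] &
      blocks$strand[hits$qid] == pts$strand[hits$sid] &
      blocks$chrom[hits$qid] == pts$chrom[hits$sid]
    data.table(frag_id = blocks$frag_id[hits$qid[ok]],
               intron_id = pts$intron_id[hits$sid[ok]], type = type)
  }
  b_ev <- cross_events(introns[, .(chrom, strand, intron_id, p = start)], "b")
  c_ev <- cross_events(introns[, .(chrom, strand, intron_id, p = end)], "c")

  unique(rbindlist(list(a_ev, b_ev, c_ev)))
}

#' Tally junction counts per intron
#'
#' @param events event table from \code{\link{junction_events}}.
#' @param introns intron table defining the output rows.
#' @return data.table(intron_id, a, b, c, jrsum), zero-filled.
#' @export
junction_counts <- function(events, introns) {
  introns <- as.data.table(introns)
  tab <- dcast(events[, .N, by = .(intron_id, type)],
               intron_id ~ type, value.var = "N", fill = 0L)
  for (col in c("a", "b", "c")) {
    if (!col %in% names(tab)) tab[, (col) := 0L]
  }
  out <- merge(introns[, .(intron_id)], tab, by = "intron_id", all.x = TRUE)
  for (col in c("a", "b", "c")) out[is.na(get(col)), (col) := 0L]
  out[, jrsum := a + b + c]
  out[]
}

#' Splicing index
#'
#' SI = a / (a + (b + c) / 2); undefined (NA) when jrsum = a + b + c is
#' below \code{min_jrsum} (default 5, guarding against unstable ratios —
#' no threshold is inherent to the definition).
#'
#' @param a,b,c junction counts (vectorized), or pass a
#'   \code{\link{junction_counts}} table as \code{a}.
#' @param min_jrsum minimum junction evidence to report an SI.
#' @return numeric SI in \[0, 1\] or NA.
#' @export
splicing_index <- function(a, b = NULL, c = NULL, min_jrsum = 5L) {
  if (is.data.frame(a)) {
    tab <- as.data.table(a)
    return(splicing_index(tab$a, tab$b, tab$c, min_jrsum = min_jrsum))
  }
  stopifnot(length(a) == length(b), length(b) == length(c),
            all(a >= 0), all(b >= 0), all(c >= 0))
  si <- ifelse(a + b + c >= min_jrsum, a / (a + (b + c) / 2), NA_real_)
  si
}

#' Splicing-index table across samples
#'
#' Counts junction events per intron and sample (replicates should be
#' merged beforehand with \code{\link{merge_fragments}}, matching the
#' convention of counting after pooling replicate reads) and reports SI
#' plus the per-sample median SI over defined introns.
#'
#' @param fsets named list of fragment_sets, one per sample.
#' @param fs a \code{\link{feature_set}}.
#' @param min_overlap,min_jrsum,mapq_min see \code{\link{junction_events}}
#'   and \code{\link{splicing_index}}.
#' @return list(records = data.table(intron_id, sample, a, b, c, jrsum,
#'   SI), medians = data.table(sample, median_SI)).
#' @export
si_table <- function(fsets, fs, min_overlap = 10L, min_jrsum = 5L,
                     mapq_min = 255L) {
  introns <- .eligible_introns(fs)
  recs <- vector("list", length(fsets))
  for (i in seq_along(fsets)) {
    ev <- junction_events(fsets[[i]], fs, introns = introns,
                          min_overlap = min_overlap, mapq_min = mapq_min)
    jc <- junction_counts(ev, introns)
    jc[, `:=`(sample = names(fsets)[i],
              SI = splicing_index(a, b, c, min_jrsum = min_jrsum))]
    recs[[i]] <- jc
  }
  records <- rbindlist(recs)
  medians <- records[!is.na(SI), .(median_SI = median(SI)), by = sample]
  list(records = records[], medians = medians[])
}

# ---- exon-spanning splicing patterns --------------------------------------
# Note on orientation: b/c are tallied at the genomic start/end of the
# intron; SI and the pattern bins are symmetric in b and c, so no
# strand-specific relabeling is needed. Exon/intron ranks, in contrast,
# are transcript-oriented (rank 1 = 5'), so "upstream intron" of internal
# exon rank e is intron rank e - 1 on either strand.

#' Exon-spanning splicing-pattern counts
#'
#' For every internal exon of a single-isoform multi-intron gene, fragments
#' that report both flanking junctions (each either split = spliced, or
#' contiguously crossing with \code{min_overlap} flanks = unspliced) are
#' binned into SS (both introns spliced), SU (upstream intron spliced
#' only), US (downstream only) and UU (both unspliced); upstream/downstream
#' are in transcript orientation. Fragments reporting only one junction, or
#' reporting a junction as both spliced and unspliced, are uninformative.
#'
#' @inheritParams si_table
#' @param fset a \code{\link{fragment_set}} (one sample, replicates
#'   merged).
#' @return data.table(exon_id, SS, SU, US, UU).
#' @export
pattern_counts <- function(fset, fs, min_overlap = 10L, mapq_min = 255L) {
  intr <- .eligible_introns(fs)
  # flanking introns per internal exon, transcript-oriented
  ex <- fs$exons[gene_id %in% unique(intr$gene_id)]
  ex[, n_ex := .N, by = tx_id]
  ex <- ex[exon_rank > 1L & exon_rank < n_ex]
  if (nrow(ex) == 0L || length(fset) == 0L) {
    return(data.table(exon_id = character(), SS = integer(), SU = integer(),
                      US = integer(), UU = integer()))
  }
  ex[, exon_id := paste0(tx_id, ".E", exon_rank)]
  flanks <- rbind(
    ex[, .(exon_id, tx_id, intron_rank = exon_rank - 1L, side = "up")],
    ex[, .(exon_id, tx_id, intron_rank = exon_rank, side = "down")])
  flanks <- merge(flanks, intr[, .(tx_id, intron_rank, intron_id)],
                  by = c("tx_id", "intron_rank"))

  ev <- junction_events(fset, fs, introns = intr,
                        min_overlap = min_overlap, mapq_min = mapq_min)
  if (nrow(ev) == 0L) {
    return(data.table(exon_id = ex$exon_id, SS = 0L, SU = 0L, US = 0L,
                      UU = 0L))
  }
  status <- ev[, .(spliced = any(type == "a"),
                   unspliced = any(type %in% c("b", "c"))),
               by = .(frag_id, intron_id)]
  status <- status[xor(spliced, unspliced)]  # conflicting evidence dropped
  status[, st := ifelse(spliced, "S", "U")]

  fe <- merge(flanks, status, by = "intron_id", allow.cartesian = TRUE)
  both <- dcast(fe, exon_id + frag_id ~ side, value.var = "st")
  both <- both[!is.na(up) & !is.na(down)]
  both[, pattern := paste0(up, down)]
  pat <- dcast(both[, .N, by = .(exon_id, pattern)], exon_id ~ pattern,
               value.var = "N", fill = 0L)
  for (col in c("SS", "SU", "US", "UU")) {
    if (!col %in% names(pat)) pat[, (col) := 0L]
  }
  out <- merge(data.table(exon_id = ex$exon_id), pat, by = "exon_id",
               all.x = TRUE)
  for (col in c("SS", "SU", "US", "UU")) out[is.na(get(col)), (col) := 0L]
  out[, .(exon_id, SS, SU, US, UU)]
}

#' Classify one fragment against one internal exon
#'
#' Single-fragment convenience wrapper around the vectorized pattern
#' machinery; returns "SS", "SU", "US", "UU" or "uninformative".
#'
#' @param fset a \code{\link{fragment_set}} containing the fragment.
#' @param frag_id the fragment id.
#' @param exon_id internal exon id (\code{<tx>.E<rank>}).
#' @param fs a \code{\link{feature_set}}.
#' @param min_overlap minimum junction overlap.
#' @return character scalar.
#' @export
classify_exon_spanning <- function(fset, frag_id, exon_id, fs,
                                   min_overlap = 10L) {
  sub <- .subset_frags(fset, frag_id)
  pc_all <- pattern_events_one(sub, fs, min_overlap)
  hit <- pc_all[pc_all$exon_id == exon_id]
  if (nrow(hit) == 0L) return("uninformative")
  hit$pattern[1L]
}

# per-(fragment, exon) patterns for a small fragment_set
pattern_events_one <- function(fset, fs, min_overlap = 10L) {
  intr <- .eligible_introns(fs)
  ex <- fs$exons[gene_id %in% unique(intr$gene_id)]
  ex[, n_ex := .N, by = tx_id]
  ex <- ex[exon_rank > 1L & exon_rank < n_ex]
  ex[, exon_id := paste0(tx_id, ".E", exon_rank)]
  flanks <- rbind(
    ex[, .(exon_id, tx_id, intron_rank = exon_rank - 1L, side = "up")],
    ex[, .(exon_id, tx_id, intron_rank = exon_rank, side = "down")])
  flanks <- merge(flanks, intr[, .(tx_id, intron_rank, intron_id)],
                  by = c("tx_id", "intron_rank"))
  ev <- junction_events(fset, fs, introns = intr, min_overlap = min_overlap,
                        mapq_min = 0L)
  if (nrow(ev) == 0L) {
    return(data.table(exon_id = character(), frag_id = integer(),
                      pattern = character()))
  }
  status <- ev[, .(spliced = any(type == "a"),
                   unspliced = any(type %in% c("b", "c"))),
               by = .(frag_id, intron_id)]
  status <- status[xor(spliced, unspliced)]
  status[, st := ifelse(spliced, "S", "U")]
  fe <- merge(flanks, status, by = "intron_id", allow.cartesian = TRUE)
  both <- dcast(fe, exon_id + frag_id ~ side, value.var = "st")
  both <- both[!is.na(up) & !is.na(down)]
  both[, pattern := paste0(up, down)]
  both[, .(exon_id, frag_id, pattern)]
}

#' Splicing-pattern fractions per sample
#'
#' Sums informative exon-spanning fragments over all eligible internal
#' exons and reports the fraction of each pattern bin; fractions sum to 1.
#'
#' @param fsets named list of fragment_sets (one per sample, replicates
#'   merged).
#' @param fs a \code{\link{feature_set}}.
#' @param min_overlap,mapq_min see \code{\link{pattern_counts}}.
#' @return data.table(sample, SS, SU, US, UU, n_informative) with
#'   fractional columns.
#' @export
pattern_fractions <- function(fsets, fs, min_overlap = 10L,
                              mapq_min = 255L) {
  out <- vector("list", length(fsets))
  for (i in seq_along(fsets)) {
    pc <- pattern_counts(fsets[[i]], fs, min_overlap = min_overlap,
                         mapq_min = mapq_min)
    tot <- pc[, sum(SS) + sum(SU) + sum(US) + sum(UU)]
    out[[i]] <- data.table(
      sample = names(fsets)[i],
      SS = if (tot > 0) pc[, sum(SS)] / tot else NA_real_,
      SU = if (tot > 0) pc[, sum(SU)] / tot else NA_real_,
      US = if (tot > 0) pc[, sum(US)] / tot else NA_real_,
      UU = if (tot > 0) pc[, sum(UU)] / tot else NA_real_,
      n_informative = tot)
  }
  rbindlist(out)
}
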