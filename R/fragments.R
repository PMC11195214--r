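#' Construct a fragment set
#'
#' A fragment set holds sequenced paired-end fragments as genomic alignment
#' blocks. Each fragment has one row in \code{frags} and one row per
#' aligned block in \code{blocks} (the unsequenced insert between mates is
#' not a block). \code{strand} is the transcription strand of the fragment
#' after protocol decoding, not the alignment orientation of either mate.
#'
#' @param frags data.table with columns \code{frag_id} (integer, unique),
#'   \code{name}, \code{chrom}, \code{strand}, \code{mapq}.
#' @param blocks data.table with columns \code{frag_id}, \code{mate}
#'   (1 or 2), \code{start}, \code{end} (0-based half-open).
#' @return object of class \code{fragment_set}.
#' @export
fragment_set <- function(frags, blocks) {
  frags <- as.data.table(frags)
  blocks <- as.data.table(blocks)
  stopifnot(all(c("frag_id", "name", "chrom", "strand", "mapq") %in% names(frags)),
            all(c("frag_id", "mate", "start", "end") %in% names(blocks)))
  if (anyDuplicated(frags$frag_id)) stop("frag_id must be unique")
  if (!all(blocks$frag_id %in% frags$frag_id)) {
    stop("blocks reference unknown frag_id")
  }
  if (nrow(blocks) && any(blocks$end <= blocks$start)) {
    stop("empty or inverted alignment block")
  }
  setorder(blocks, frag_id, start)
  setorder(frags, frag_id)
  structure(list(frags = frags, blocks = blocks), class = "fragment_set")
}

#' @export
length.fragment_set <- function(x) nrow(x$frags)

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments, %d aligned blocks on %d chromosome(s)\n",
              nrow(x$frags), nrow(x$blocks), length(unique(x$frags$chrom))))
  invisible(x)
}

# subset a fragment_set by frag_id
.subset_frags <- function(fset, ids) {
  fragment_set(fset$frags[frag_id %in% ids],
               fset$blocks[frag_id %in% ids])
}

#' Merge fragment sets (e.g. replicates before junction counting)
#'
#' @param ... fragment_set objects.
#' @return a single fragment_set with renumbered fragment ids.
#' @export
merge_fragments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "fragment_set")) {
    sets <- sets[[1]]
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "fragment_set")))
  offset <- 0L
  fr <- vector("list", length(sets))
  bl <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    f <- copy(sets[[i]]$frags)
    b <- copy(sets[[i]]$blocks)
    f[, frag_id := frag_id + offset]
    b[, frag_id := frag_id + offset]
    offset <- offset + max(c(0L, sets[[i]]$frags$frag_id))
    fr[[i]] <- f
    bl[[i]] <- b
  }
  fragment_set(rbindlist(fr), rbindlist(bl))
}

# ---- SAM I/O ---------------------------------------------------------------
# Records are written one per mate with CIGAR M/N ops; the transcription
# strand is encoded via mate orientations under the dUTP ("reverse")
# convention: the transcription strand is the opposite of the first mate's
# alignment strand.

#' Write a fragment set as a coordinate-sorted SAM file
#'
#' @param fset a \code{\link{fragment_set}}.
#' @param path output SAM path.
#' @param chrom_lengths named integer vector of reference lengths; inferred
#'   from the data (max end + 1000) when NULL.
#' @export
write_sam <- function(fset, path, chrom_lengths = NULL) {
  stopifnot(inherits(fset, "fragment_set"))
  b <- copy(fset$blocks)
  f <- fset$frags
  b <- merge(b, f[, .(frag_id, name, chrom, strand, mapq)], by = "frag_id")
  if (is.null(chrom_lengths)) {
    cl <- b[, .(len = max(end) + 1000L), by = chrom]
    chrom_lengths <- setNames(cl$len, cl$chrom)
  }
  setorder(b, frag_id, mate, start)
  # per (frag, mate): pos, cigar
  rec <- b[, {
    gaps <- if (.N > 1L) start[-1L] - end[-.N] else integer()
    if (any(gaps < 0L)) stop("overlapping blocks within one mate")
    cig <- paste0(end - start, "M")
    if (.N > 1L) {
      cig <- c(rbind(cig[-.N], paste0(gaps, "N")), cig[.N])
    }
    list(pos = start[1L] + 1L, endg = end[.N],
         cigar = paste(cig, collapse = ""))
  }, by = .(frag_id, mate, name, chrom, strand, mapq)]
  wide <- dcast(rec, frag_id + name + chrom + strand + mapq ~ mate,
                value.var = c("pos", "endg", "cigar"))
  # mate alignment orientation under the reverse (dUTP) protocol:
  # first mate aligns opposite to the transcript strand
  m1rev <- wide$strand == "+"
  flag1 <- 1L + 2L + 64L + ifelse(m1rev, 16L, 32L)
  flag2 <- 1L + 2L + 128L + ifelse(m1rev, 32L, 16L)
  span <- pmax(wide$endg_1, wide$endg_2) - pmin(wide$pos_1, wide$pos_2) + 1L
  tlen1 <- ifelse(wide$pos_1 <= wide$pos_2, span, -span)
  lines1 <- paste(wide$name, flag1, wide$chrom, wide$pos_1, wide$mapq,
                  wide$cigar_1, "=", wide$pos_2, tlen1, "*", "*", sep = "\t")
  lines2 <- paste(wide$name, flag2, wide$chrom, wide$pos_2, wide$mapq,
                  wide$cigar_2, "=", wide$pos_1, -tlen1, "*", "*", sep = "\t")
  body <- data.table(chrom = rep(wide$chrom, 2L),
                     pos = c(wide$pos_1, wide$pos_2),
                     line = c(lines1, lines2))
  setorder(body, chrom, pos)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  con <- file(path, open = "wb")  # binary mode: fixed "\n" on any platform
  on.exit(close(con))
  writeLines(c(hdr, body$line), con, sep = "\n")
  invisible(path)
}

#' Read a SAM file of paired-end alignments as a fragment set
#'
#' Parses the 11 mandatory SAM columns; CIGAR ops M/=/X/D extend aligned
#' blocks, N splits them, S/I/H/P consume no reference. Unpaired records
#' are dropped. The transcription strand is decoded from the first mate's
#' orientation according to \code{strandedness}: \code{"reverse"}
#' (dUTP-style, default) flips it, \code{"forward"} keeps it.
#'
#' @param path SAM file.
#' @param strandedness \code{"reverse"} or \code{"forward"}.
#' @return a \code{\link{fragment_set}}.
#' @export
read_sam <- function(path, strandedness = c("reverse", "forward")) {
  strandedness <- match.arg(strandedness)
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(fragment_set(
      data.table(frag_id = integer(), name = character(), chrom = character(),
                 strand = character(), mapq = integer()),
      data.table(frag_id = integer(), mate = integer(), start = integer(),
                 end = integer())))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:9)
  rec <- data.table(qname = fields[[1]], flag = as.integer(fields[[2]]),
                    chrom = fields[[3]], pos = as.integer(fields[[4]]) - 1L,
                    mapq = as.integer(fields[[5]]), cigar = fields[[6]])
  rec <- rec[bitwAnd(flag, 4L) == 0L]               # drop unmapped
  rec[, mate := ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)]
  rec[, rev := bitwAnd(flag, 16L) > 0L]
  rec[, rec_id := .I]

  # expand CIGAR into per-op rows
  ops <- regmatches(rec$cigar, gregexpr("\\d+[MIDNSHP=X]", rec$cigar))
  nop <- lengths(ops)
  opv <- unlist(ops, use.names = FALSE)
  opdt <- data.table(rec_id = rep(rec$rec_id, nop),
                     len = as.integer(sub("[MIDNSHP=X]$", "", opv)),
                     op = sub("^\\d+", "", opv))
  opdt[, consumes := op %in% c("M", "=", "X", "D", "N")]
  opdt[, off := cumsum(c(0L, head(len * consumes, -1L))), by = rec_id]
  opdt <- merge(opdt, rec[, .(rec_id, pos)], by = "rec_id")
  opdt[, `:=`(gstart = pos + off, gend = pos + off + len * consumes)]
  aligned <- opdt[op %in% c("M", "=", "X", "D")]
  # merge ops contiguous on the reference into blocks (split only at N)
  aligned[, newblk := c(1L, as.integer(gstart[-1L] != gend[-.N])), by = rec_id]
  aligned[, blk := cumsum(newblk), by = rec_id]
  blocks_rec <- aligned[, .(start = min(gstart), end = max(gend)),
                        by = .(rec_id, blk)]

  # pair mates into fragments
  rec[, frag_key := qname]
  keymap <- rec[, .(n = .N), by = frag_key]
  rec <- rec[frag_key %in% keymap[n == 2L, frag_key]]
  if (nrow(rec) == 0L) stop("no complete read pairs in ", path)
  fid <- rec[, .(frag_id = .GRP, chrom = chrom[1L], mapq = min(mapq),
                 m1rev = rev[mate == 1L][1L]), by = frag_key]
  if (strandedness == "reverse") {
    fid[, strand := ifelse(m1rev, "+", "-")]
  } else {
    fid[, strand := ifelse(m1rev, "-", "+")]
  }
  rec <- merge(rec, fid[, .(frag_key, frag_id)], by = "frag_key")
  blk <- merge(blocks_rec, rec[, .(rec_id, frag_id, mate)], by = "rec_id")
  fragment_set(
    frags = fid[, .(frag_id, name = frag_key, chrom, strand, mapq)],
    blocks = blk[, .(frag_id, mate, start, end)])
}
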