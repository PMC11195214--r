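# Transcript-isoform dynamics: fragments are collapsed into equivalence
# classes (the set of isoforms whose exon structure they are compatible
# with), quantified by EM, and each gene's isoform-percentage series over
# the chase is classified into dominance trajectories.

#' Build equivalence-class counts for a gene
#'
#' A mate is compatible with an isoform iff all its blocks lie inside that
#' isoform's exons and every within-mate split matches one of the
#' isoform's introns exactly; a fragment is compatible iff both mates are.
#' The class of a fragment is its set of compatible isoforms; fragments
#' compatible with none (e.g. lying in a retained intron) are tallied as
#' incompatible.
#'
#' @param fset a \code{\link{fragment_set}} (replicates merged per
#'   timepoint).
#' @param fs a \code{\link{feature_set}}.
#' @param gene_id gene to quantify.
#' @param frag_mean mean fragment length, for the effective length
#'   (transcript length - frag_mean + 1, floored at 1).
#' @param mapq_min minimum mapping quality.
#' @return list(classes = data.table(class, n) with class a sorted
#'   "|"-joined isoform set, eff_len = named numeric, incompatible =
#'   integer, total = fragments considered).
#' @export
build_equivalence_classes <- function(fset, fs, gene_id, frag_mean = 450,
                                      mapq_min = 255L) {
  stopifnot(inherits(fset, "fragment_set"), inherits(fs, "feature_set"))
  gid <- gene_id
  g <- fs$genes[gene_id == gid]
  if (nrow(g) != 1L) stop("unknown gene: ", gid)
  txs <- fs$transcripts[gene_id == gid, tx_id]
  keep <- fset$frags[mapq >= mapq_min & chrom == g$chrom & strand == g$strand]
  blocks <- fset$blocks[frag_id %in% keep$frag_id]
  # restrict to fragments overlapping the gene span
  span <- blocks[, .(mn = min(start), mx = max(end)), by = frag_id]
  ids <- span[mx > g$start & mn < g$end, frag_id]
  blocks <- blocks[frag_id %in% ids]
  blocks <- copy(blocks)[, chrom := g$chrom]  # all retained frags share it
  setorder(blocks, frag_id, mate, start)

  exlen <- fs$exons[tx_id %in% txs, .(len = sum(end - start)), by = tx_id]
  eff_len <- setNames(pmax(exlen$len - frag_mean + 1, 1), exlen$tx_id)[txs]

  if (length(ids) == 0L) {
    return(list(classes = data.table(class = character(), n = integer()),
                eff_len = eff_len, incompatible = 0L, total = 0L))
  }

  compat <- matrix(FALSE, nrow = length(ids), ncol = length(txs),
                   dimnames = list(NULL, txs))
  for (j in seq_along(txs)) {
    ex <- fs$exons[tx_id == txs[j]]
    intr <- fs$introns[tx_id == txs[j]]
    # blocks fully inside an exon of this isoform
    hits <- interval_overlaps(blocks, ex)
    inside <- rep(FALSE, nrow(blocks))
    if (nrow(hits) > 0L) {
      ok <- blocks$start[hits$qid] >= ex$start[hits$sid] &
        blocks$end[hits$qid] <= ex$end[hits$sid]
      inside[unique(hits$qid[ok])] <- TRUE
    }
    bl_ok <- blocks[, .(all_inside = all(inside[.I])), by = frag_id]
    # within-mate splits must match this isoform's introns
    gaps <- blocks[, if (.N > 1L)
      .(gstart = end[-.N], gend = start[-1L]), by = .(frag_id, mate)]
    if (nrow(gaps) > 0L) {
      if (nrow(intr) > 0L) {
        gaps[, match_intron := paste(gstart, gend) %in%
               paste(intr$start, intr$end)]
      } else {
        gaps[, match_intron := FALSE]
      }
      gap_ok <- gaps[, .(gaps_ok = all(match_intron)), by = frag_id]
      bl_ok <- merge(bl_ok, gap_ok, by = "frag_id", all.x = TRUE)
      bl_ok[is.na(gaps_ok), gaps_ok := TRUE]
      bl_ok[, all_inside := all_inside & gaps_ok]
    }
    compat[match(bl_ok$frag_id, ids), j] <- bl_ok$all_inside
  }
  any_compat <- rowSums(compat) > 0L
  cls <- apply(compat[any_compat, , drop = FALSE], 1L, function(x)
    paste(sort(txs[x]), collapse = "|"))
  classes <- as.data.table(table(class = cls))
  setnames(classes, "N", "n")
  list(classes = classes[, .(class, n = as.integer(n))],
       eff_len = eff_len,
       incompatible = sum(!any_compat), total = length(ids))
}

#' Equivalence-class EM quantification
#'
#' Maximizes the standard length-normalized equivalence-class likelihood
#' \deqn{L(\theta) = \sum_c n_c \log \sum_{t \in c} \theta_t / \ell_t}
#' by EM from a uniform start: responsibilities proportional to
#' \eqn{\theta_t/\ell_t} within each class, then
#' \eqn{\theta_t \propto \sum_c n_c r_{tc}}. Iteration stops when
#' \code{max |delta theta| < tol} or at \code{max_iter} (with a warning
#' flag in attribute \code{"converged"}).
#'
#' @param ec result of \code{\link{build_equivalence_classes}}, or a
#'   data.table(class, n).
#' @param eff_len named effective lengths (required if \code{ec} is a
#'   table).
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 1000).
#' @return named numeric simplex over isoforms, with attributes
#'   \code{"iterations"}, \code{"converged"}, \code{"loglik"}.
#' @export
em_quantify <- function(ec, eff_len = NULL, tol = 1e-8, max_iter = 1000L) {
  if (is.list(ec) && !is.data.frame(ec) && !is.null(ec$classes)) {
    eff_len <- ec$eff_len
    ec <- ec$classes
  }
  ec <- as.data.table(ec)
  stopifnot(!is.null(eff_len), all(eff_len > 0), sum(ec$n) > 0)
  txs <- names(eff_len)
  members <- strsplit(ec$class, "|", fixed = TRUE)
  if (!all(unlist(members) %in% txs)) stop("class references unknown isoform")
  memb_idx <- lapply(members, match, txs)
  n <- ec$n
  K <- length(txs)
  theta <- rep(1 / K, K)
  inv_l <- 1 / eff_len
  loglik <- function(th) {
    sum(n * log(vapply(memb_idx, function(ix) sum(th[ix] * inv_l[ix]),
                       numeric(1))))
  }
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    new <- numeric(K)
    for (ci in seq_along(memb_idx)) {
      ix <- memb_idx[[ci]]
      w <- theta[ix] * inv_l[ix]
      new[ix] <- new[ix] + n[ci] * w / sum(w)
    }
    new <- new / sum(new)
    delta <- max(abs(new - theta))
    theta <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  structure(setNames(theta, txs), iterations = it, converged = converged,
            loglik = loglik(theta))
}

#' Isoform percentages and TPM across timepoints
#'
#' Quantifies every gene with at least \code{min_isoforms} isoforms at each
#' timepoint and reports isoform percentages (100 x EM proportion) and
#' TPM. Genes are retained only if their total expression at the first
#' (0h) timepoint is at least \code{tpm_min} (default 1 TPM).
#'
#' @param fsets_by_tp named list (by timepoint label, 0h first) of
#'   \code{\link{fragment_set}} objects with replicates merged.
#' @param fs a \code{\link{feature_set}}.
#' @param genes genes to quantify; default all genes with >=
#'   \code{min_isoforms} isoforms.
#' @param tpm_min expression filter at the first timepoint.
#' @param min_isoforms minimum annotated isoforms (default 2).
#' @param frag_mean,mapq_min see \code{\link{build_equivalence_classes}}.
#' @return data.table(gene_id, tx_id, timepoint, tpm, isoform_percentage).
#' @export
isoform_percentages <- function(fsets_by_tp, fs, genes = NULL, tpm_min = 1,
                                min_isoforms = 2L, frag_mean = 450,
                                mapq_min = 255L) {
  if (is.null(genes)) genes <- fs$genes[n_tx >= min_isoforms, gene_id]
  genes <- intersect(genes, fs$genes[n_tx >= min_isoforms, gene_id])
  tps <- names(fsets_by_tp)
  rows <- list()
  for (tp in tps) {
    fset <- fsets_by_tp[[tp]]
    for (g in genes) {
      ec <- build_equivalence_classes(fset, fs, g, frag_mean = frag_mean,
                                      mapq_min = mapq_min)
      if (sum(ec$classes$n) == 0L) {
        theta <- setNames(rep(NA_real_, length(ec$eff_len)),
                          names(ec$eff_len))
        rate <- setNames(rep(0, length(ec$eff_len)), names(ec$eff_len))
      } else {
        theta <- em_quantify(ec)
        # expected fragments per isoform under length-weighted generation,
        # converted to a molar rate for TPM
        nfrag <- sum(ec$classes$n)
        rate <- nfrag * theta / sum(theta * ec$eff_len)
      }
      rows[[length(rows) + 1L]] <- data.table(
        gene_id = g, tx_id = names(ec$eff_len), timepoint = tp,
        rate = as.numeric(rate),
        isoform_percentage = 100 * as.numeric(theta))
    }
  }
  out <- rbindlist(rows)
  out[, tpm := 1e6 * rate / sum(rate), by = timepoint]
  out[, rate := NULL]
  # expression filter at the first timepoint
  tp0 <- tps[1L]
  keep <- out[timepoint == tp0, .(tot = sum(tpm)), by = gene_id][
    tot >= tpm_min, gene_id]
  out <- out[gene_id %in% keep]
  out[]
}

#' Classify a gene's isoform-dominance trajectory
#'
#' An isoform with percentage >= \code{threshold} (default 50) at a
#' timepoint is dominant there. The gene is AD (always dominant) if some
#' isoform is dominant at all timepoints; GD (gained dominance) if some
#' isoform is below the threshold at the first timepoint and dominant at
#' the last; LD (lost dominance) for the converse. GD and LD can co-occur
#' (different isoforms trading places); a gene matching none is "other".
#'
#' @param pct matrix isoforms x timepoints of isoform percentages (columns
#'   ordered 0h first), or a data.table from
#'   \code{\link{isoform_percentages}} restricted to one gene.
#' @param threshold dominance threshold in percent (default 50).
#' @return list(AD, GD, LD logicals; category string; dominant = named
#'   list of dominant isoform(s) per timepoint).
#' @export
dominance_classify <- function(pct, threshold = 50) {
  if (is.data.frame(pct)) {
    dt <- as.data.table(pct)
    pct <- as.matrix(dcast(dt, tx_id ~ timepoint, value.var =
                             "isoform_percentage")[, -1L])
    rownames(pct) <- unique(sort(dt$tx_id))
  }
  if (anyNA(pct)) {
    return(list(AD = NA, GD = NA, LD = NA, category = "unclassifiable",
                dominant = NULL))
  }
  first <- pct[, 1L]
  last <- pct[, ncol(pct)]
  ad <- any(rowSums(pct >= threshold) == ncol(pct))
  gd <- any(first < threshold & last >= threshold)
  ld <- any(first >= threshold & last < threshold)
  category <- if (ad && !gd && !ld) "AD"
  else if (gd && ld) "GD+LD"
  else if (gd) "GD"
  else if (ld) "LD"
  else if (ad) "AD"
  else "other"
  dominant <- apply(pct >= threshold, 2L, function(x)
    rownames(pct)[x], simplify = FALSE)
  list(AD = ad, GD = gd, LD = ld, category = category, dominant = dominant)
}

#' Dominance-category summary over genes
#'
#' @param pct_table output of \code{\link{isoform_percentages}}.
#' @param threshold dominance threshold in percent.
#' @return list(calls = data.table(gene_id, AD, GD, LD, category),
#'   fractions = named fractions of classified genes per category; AD/GD/LD
#'   fractions count every gene carrying that flag, so they need not sum
#'   to 1).
#' @export
dominance_summary <- function(pct_table, threshold = 50) {
  pct_table <- as.data.table(pct_table)
  genes <- unique(pct_table$gene_id)
  calls <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    d <- dominance_classify(pct_table[gene_id == genes[i]],
                            threshold = threshold)
    calls[[i]] <- data.table(gene_id = genes[i], AD = d$AD, GD = d$GD,
                             LD = d$LD, category = d$category)
  }
  calls <- rbindlist(calls)
  done <- calls[category != "unclassifiable"]
  fractions <- c(AD = mean(done$AD), GD = mean(done$GD), LD = mean(done$LD),
                 other = mean(done$category == "other"))
  list(calls = calls[], fractions = fractions)
}
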