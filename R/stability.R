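# Per-gene relative stability over chase intervals. The DESeq2 route of
# the original protocol is replaced by an implemented estimator:
# median-of-ratios size factors, pseudocount 0.5, a Wald test on the log2
# fold change under a negative-binomial model with method-of-moments
# dispersion (floored), and Benjamini-Hochberg correction.

#' Median-of-ratios size factors
#'
#' DESeq2-style normalization: for each sample, the median over genes of
#' the ratio of the gene's count to its geometric mean across samples;
#' genes with a zero anywhere are excluded from the median. Note that this
#' equalizes the median gene between samples, which in a chase experiment
#' (where every labeled transcript decays) makes downstream fold changes
#' *relative* to the median gene's decay — see
#' \code{\link{stability_log2fc}}'s \code{normalization} argument.
#'
#' @param counts numeric matrix genes x samples, or a
#'   \code{\link{exonic_count_matrix}} object.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    stop("no gene has nonzero counts in all samples; ",
         "consider a pseudo-reference fallback")
  }
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  apply(lc, 2L, function(x) exp(median(x - ref)))
}

#' Reads per kilobase per million
#'
#' @param count fragment count(s).
#' @param gene_length feature length in bases.
#' @param library_size total fragments in the sample.
#' @return numeric RPKM.
#' @export
rpkm <- function(count, gene_length, library_size) {
  count / (gene_length / 1e3) / (library_size / 1e6)
}

#' Relative stability (log2 fold change) over a chase interval
#'
#' For each gene passing an expression filter (RPKM above
#' \code{rpkm_min} at the earlier timepoint), the log2 fold change of mean
#' normalized counts between the later and earlier timepoint, with a Wald
#' p-value from a negative-binomial model (method-of-moments dispersion,
#' floored at \code{dispersion_floor}) and BH-adjusted p across reported
#' genes. Negative log2FC means the transcript decayed over the interval.
#'
#' @param cm a \code{\link{exonic_count_matrix}}.
#' @param interval \code{"early"} (2h vs 0h) or \code{"late"} (6h vs 2h);
#'   or a length-2 numeric of (earlier, later) timepoints.
#' @param rpkm_min expression filter at the earlier timepoint (default
#'   0.5, applied as strictly-greater).
#' @param normalization \code{"median_ratio"} (default): median-of-ratios
#'   size factors over the samples of the two timepoints; fold changes are
#'   then relative to the median gene. \code{"none"}: counts are taken on
#'   their absolute scale, appropriate when the library preserves labeled
#'   RNA abundance (spike-in or capture-anchored libraries, or the
#'   simulator's anchored mode); required for absolute decay-rate
#'   recovery, since with every gene decaying the median gene is itself
#'   decaying.
#' @param pseudocount added to mean counts before the ratio (default 0.5).
#' @param dispersion_floor minimum NB dispersion (default 0.01).
#' @return data.table(gene, interval, baseMean, log2FC, SE, p, padj,
#'   rpkm_earlier).
#' @export
stability_log2fc <- function(cm, interval = c("early", "late"),
                             rpkm_min = 0.5,
                             normalization = c("median_ratio", "none"),
                             pseudocount = 0.5, dispersion_floor = 0.01) {
  stopifnot(inherits(cm, "count_matrix"))
  normalization <- match.arg(normalization)
  tps <- sort(unique(cm$samples$timepoint))
  if (is.character(interval)) {
    interval <- match.arg(interval)
    if (length(tps) < 3L && interval == "late") {
      stop("late interval needs three timepoints, have: ",
           paste(tps, collapse = ", "))
    }
    pair <- if (interval == "early") tps[1:2] else tps[2:3]
    label <- interval
  } else {
    stopifnot(length(interval) == 2L)
    pair <- interval
    label <- paste0(pair[1], "h_vs_", pair[2], "h")
  }
  sel <- cm$samples$timepoint %in% pair
  if (!all(pair %in% cm$samples$timepoint)) {
    stop("missing timepoint for interval: ", paste(pair, collapse = ", "))
  }
  counts <- cm$counts[, sel, drop = FALSE]
  meta <- cm$samples[sel]
  n_e <- sum(meta$timepoint == pair[1])
  n_l <- sum(meta$timepoint == pair[2])
  few_reps <- n_e < 2L || n_l < 2L
  if (few_reps) {
    warning("fewer than 2 replicates in a group; p-values not computed")
  }

  sf <- switch(normalization,
               median_ratio = size_factors(counts),
               none = rep(1, ncol(counts)))
  norm <- sweep(counts, 2L, sf, "/")
  e_cols <- meta$timepoint == pair[1]
  l_cols <- meta$timepoint == pair[2]
  mu_e <- rowMeans(norm[, e_cols, drop = FALSE])
  mu_l <- rowMeans(norm[, l_cols, drop = FALSE])
  log2fc <- log2((mu_l + pseudocount) / (mu_e + pseudocount))

  # expression filter on raw counts of the earlier timepoint
  lib <- colSums(counts)
  rpkm_mat <- rpkm(counts[, e_cols, drop = FALSE],
                   gene_length = cm$lengths,
                   library_size = rep(lib[e_cols], each = nrow(counts)))
  rpkm_e <- rowMeans(rpkm_mat)
  keep <- rpkm_e > rpkm_min

  # method-of-moments NB dispersion from within-group moments
  disp_grp <- function(mat) {
    m <- rowMeans(mat)
    v <- apply(mat, 1L, var)
    (v - m) / pmax(m, 1e-8)^2
  }
  if (!few_reps) {
    alpha <- pmax((disp_grp(norm[, e_cols, drop = FALSE]) +
                   disp_grp(norm[, l_cols, drop = FALSE])) / 2,
                  dispersion_floor)
    v_log <- (1 / pmax(mu_e, pseudocount) + alpha) / n_e +
      (1 / pmax(mu_l, pseudocount) + alpha) / n_l
    se <- sqrt(v_log) / log(2)
    p <- 2 * pnorm(-abs(log2fc / se))
  } else {
    se <- rep(NA_real_, length(log2fc))
    p <- rep(NA_real_, length(log2fc))
  }

  out <- data.table(gene = rownames(cm$counts), interval = label,
                    baseMean = (mu_e + mu_l) / 2, log2FC = log2fc,
                    SE = se, p = p, rpkm_earlier = rpkm_e)[keep]
  out[, padj := p.adjust(p, method = "BH")]
  setorder(out, gene)
  out[]
}

#' Rescale a log2FC vector to the unit interval
#'
#' (x - min) / (max - min); 1 is the most stable gene of the set, 0 the
#' least stable. Affine-invariant and order-preserving.
#'
#' @param values numeric vector with at least two distinct values.
#' @return numeric vector in \[0, 1\].
#' @export
rescale_unit <- function(values) {
  stopifnot(length(values) >= 2L)
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2]) stop("cannot rescale a constant vector")
  (values - r[1]) / (r[2] - r[1])
}

#' Two-interval stability trajectories across cell lines
#'
#' For genes passing the expression filter in *all* cell lines, the
#' early-interval and late-interval log2FC values are rescaled to \[0, 1\]
#' per cell line and emitted as one point per (gene, cell line), plus the
#' across-cell-line mean ("averaged"). Points near (1,1) are stable over
#' both intervals; below the diagonal means early-stable/late-unstable.
#'
#' @param early,late named lists (by cell line) of
#'   \code{\link{stability_log2fc}} tables.
#' @return data.table(gene, cell_line, scaled_early, scaled_late).
#' @export
trajectory_matrix <- function(early, late) {
  stopifnot(length(early) == length(late),
            identical(names(early), names(late)))
  shared <- Reduce(intersect, c(lapply(early, `[[`, "gene"),
                                lapply(late, `[[`, "gene")))
  if (length(shared) < 2L) stop("fewer than 2 genes pass in all cell lines")
  pts <- vector("list", length(early))
  for (i in seq_along(early)) {
    e <- as.data.table(early[[i]])[gene %in% shared][order(gene)]
    l <- as.data.table(late[[i]])[gene %in% shared][order(gene)]
    pts[[i]] <- data.table(gene = e$gene, cell_line = names(early)[i],
                           scaled_early = rescale_unit(e$log2FC),
                           scaled_late = rescale_unit(l$log2FC))
  }
  out <- rbindlist(pts)
  avg <- out[, .(cell_line = "averaged",
                 scaled_early = mean(scaled_early),
                 scaled_late = mean(scaled_late)), by = gene]
  rbind(out, avg[, .(gene, cell_line, scaled_early, scaled_late)])
}

#' Cell-line correlation of stability values
#'
#' Pearson correlation of per-gene log2FC between cell lines over their
#' shared genes, with average-linkage hierarchical clustering on 1 - r.
#'
#' @param tables named list (by cell line) of \code{\link{stability_log2fc}}
#'   tables for one interval.
#' @return list(r = correlation matrix, hclust, order).
#' @export
cellline_correlation <- function(tables) {
  stopifnot(length(tables) >= 2L)
  shared <- Reduce(intersect, lapply(tables, `[[`, "gene"))
  mat <- vapply(tables, function(tb) {
    tb <- as.data.table(tb)[gene %in% shared][order(gene)]
    tb$log2FC
  }, numeric(length(shared)))
  r <- cor(mat, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  list(r = r, hclust = hc, order = colnames(r)[hc$order])
}
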