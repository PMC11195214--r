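# Generative model of a labeling/chase experiment.
#
# A 30-min label is collapsed to an instantaneous cohort born at t = 0.
# Each molecule draws its splice state once at synthesis: with probability
# p_allnone it follows the all-or-none mode (fully spliced with probability
# q_spliced, else fully unspliced); otherwise each intron i is spliced
# independently with probability s_i. Survival to the chase timepoint is
# filtered per state: fully spliced molecules decay with a biphasic mature
# rate (k_early over 0-2h, k_late after), everything else decays with
# k_unspliced and converts to the fully spliced pool at rate r_post
# (post-transcriptional splicing). Excised introns are separate molecules
# decaying with k_intron. Non-genic classes (PROMPT/eRNA/readthrough) are
# unspliced single-interval molecules with class-level rates.

#' Simulate a compact gene annotation
#'
#' Lays `n_genes` non-overlapping genes on one synthetic chromosome with
#' realistic exon/intron sizes. The first `n_two_isoform` genes get a
#' second isoform that skips one internal exon (a distinguishing junction
#' for isoform quantification); all others are single-isoform. Intergenic
#' enhancer and repeat intervals are placed in the gaps between genes.
#'
#' @param n_genes number of genes.
#' @param n_two_isoform how many of them carry a skipped-exon second isoform.
#' @param seed RNG seed.
#' @param n_exon_range,exon_range,intron_range integer ranges (min,max) for
#'   exon count per transcript, exon length and intron length. Defaults:
#'   4-8 exons, 150-400 bp exons, 600-2000 bp introns.
#' @param gene_gap intergenic spacing in bases (default 30000, leaving room
#'   for PROMPT/readthrough windows).
#' @param chrom chromosome name.
#' @param n_enhancers,n_repeats how many intergenic enhancer/repeat
#'   intervals to scatter.
#' @param isoform_mode \code{"skip"}: the second isoform skips an internal
#'   exon (isoforms differ in length). \code{"alt"}: the second isoform
#'   swaps the exon for a mutually exclusive one of identical length
#'   placed in the downstream intron (equal-length isoforms with
#'   symmetric unique regions).
#' @return a \code{\link{feature_set}}.
#' @export
sim_annotation <- function(n_genes = 30L, n_two_isoform = 6L, seed = 1L,
                           n_exon_range = c(4L, 8L),
                           exon_range = c(150L, 400L),
                           intron_range = c(600L, 2000L),
                           gene_gap = 30000L, chrom = "chrS1",
                           n_enhancers = 8L, n_repeats = 12L,
                           isoform_mode = c("skip", "alt")) {
  stopifnot(n_two_isoform <= n_genes)
  isoform_mode <- match.arg(isoform_mode)
  set.seed(derive_seed(seed, "annotation"))
  pos <- 50000L
  ex_list <- vector("list", n_genes)
  gap_mids <- integer()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%03d", g)
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_ex <- sample(seq(n_exon_range[1], n_exon_range[2]), 1L)
    exlen <- sample(seq(exon_range[1], exon_range[2]), n_ex, replace = TRUE)
    inlen <- if (n_ex > 1L)
      sample(seq(intron_range[1], intron_range[2]), n_ex - 1L, replace = TRUE)
      else integer()
    starts <- pos + cumsum(c(0L, head(exlen, -1L) + inlen))
    ends <- starts + exlen
    tx1 <- data.table(gene_id = gid, tx_id = paste0(gid, ".t1"),
                      chrom = chrom, strand = strand,
                      start = starts, end = ends)
    ex_list[[g]] <- tx1
    if (g <= n_two_isoform && n_ex >= 4L) {
      skip <- sample(2:(n_ex - 1L), 1L)  # internal exon varied in isoform 2
      if (isoform_mode == "skip") {
        tx2 <- copy(tx1[-skip])
      } else {
        # mutually exclusive exon of identical length placed inside the
        # following intron: isoforms have equal length and symmetric
        # unique regions, so equivalence-class EM is unbiased by design
        tx2 <- copy(tx1)
        elen <- tx2$end[skip] - tx2$start[skip]
        alt_start <- tx2$end[skip] + 150L
        if (alt_start + elen + 150L > tx1$start[skip + 1L]) {
          alt_start <- tx2$end[skip] + 50L  # tight intron fallback
        }
        tx2[skip, `:=`(start = alt_start, end = alt_start + elen)]
      }
      tx2[, tx_id := paste0(gid, ".t2")]
      ex_list[[g]] <- rbind(tx1, tx2)
    }
    gap_mids <- c(gap_mids, max(ends) + as.integer(gene_gap / 2))
    pos <- max(ends) + gene_gap
  }
  ex <- rbindlist(ex_list)

  mk_regions <- function(n, prefix, width_range) {
    mids <- sample(gap_mids, min(n, length(gap_mids)))
    w <- sample(seq(width_range[1], width_range[2]), length(mids),
                replace = TRUE)
    data.table(family = sprintf("%s%02d", prefix, seq_along(mids)),
               chrom = chrom,
               strand = sample(c("+", "-"), length(mids), replace = TRUE),
               start = as.integer(mids - w %/% 2L),
               end = as.integer(mids + w %/% 2L))
  }
  enh <- if (n_enhancers > 0L) mk_regions(n_enhancers, "ENH", c(400L, 1200L)) else NULL
  reps <- if (n_repeats > 0L) {
    r <- mk_regions(n_repeats, "R", c(400L, 1200L))
    r[, family := sample(c("L1", "Alu", "LTR", "MIR"), .N, replace = TRUE)]
    r
  } else NULL
  feature_set(ex, repeats = reps, enhancers = enh)
}

#' Draw ground-truth kinetic parameters for a simulated experiment
#'
#' Defaults describe a 30-min label followed by a 0/2/6h chase:
#' mature decay rates uniform on (0, ln 2) per hour (half-lives of 1h and
#' up), fully unspliced molecules purged with a 40-min half-life, excised
#' introns with a 30-min half-life, a dominant all-or-none splicing mode
#' (p_allnone = 0.8) with half the molecules born fully spliced
#' (q_spliced = 0.5), per-intron co-transcriptional splicing probabilities
#' Beta(2,2) for the independent minority, and class RNA turnover ordered
#' PROMPT ~ eRNA < readthrough in stability.
#'
#' @param fs a \code{\link{feature_set}} (typically \code{\link{sim_annotation}}).
#' @param seed RNG seed.
#' @param synthesis_mean mean expected labeled molecules per gene at 0h
#'   (lognormal across genes).
#' @param synthesis_sd lognormal sdlog of synthesis levels across genes.
#' @param k_early_range,k_late_range uniform ranges (per hour) for the
#'   early (0-2h) and late (2-6h) mature decay rates.
#' @param k_unspliced,k_intron,r_post rates (per hour) for unspliced purge,
#'   excised-intron decay and post-transcriptional splicing conversion.
#' @param p_allnone probability a molecule follows the all-or-none mode.
#' @param q_spliced probability an all-or-none molecule is born fully
#'   spliced.
#' @param s_beta shape parameters of the Beta distribution for per-intron
#'   independent splicing probabilities, or a single numeric in \[0,1\] to
#'   fix all s_i.
#' @param isoform_props NULL for a Beta(6,3) draw of the major-isoform
#'   share in two-isoform genes, or a length-2 numeric simplex applied to
#'   all of them.
#' @param isoform_k_late NULL to reuse the gene's late rate for both
#'   isoforms, or "flip" to give the minor isoform a stable late phase and
#'   the major isoform a fast one (drives dominance switches).
#' @param class_rates named rates per hour for the non-genic classes.
#' @param class_level_mean mean molecules per non-genic region at 0h.
#' @return object of class \code{sim_truth}.
#' @export
sim_params <- function(fs, seed = 1L, synthesis_mean = 150,
                       synthesis_sd = 0.6,
                       k_early_range = c(0, log(2)),
                       k_late_range = c(0, log(2)),
                       k_unspliced = 1.0, k_intron = 1.4, r_post = 0.3,
                       p_allnone = 0.8, q_spliced = 0.5, s_beta = c(2, 2),
                       isoform_props = NULL, isoform_k_late = NULL,
                       class_rates = c(prompt = 1.4, eRNA = 1.4,
                                       readthrough = 0.8),
                       class_level_mean = 40) {
  stopifnot(inherits(fs, "feature_set"))
  set.seed(derive_seed(seed, "params"))
  g <- fs$genes[order(gene_id)]
  genes <- data.table(
    gene_id = g$gene_id,
    synthesis_level = rlnorm(nrow(g), log(synthesis_mean), synthesis_sd),
    k_early = runif(nrow(g), k_early_range[1], k_early_range[2]),
    k_late = runif(nrow(g), k_late_range[1], k_late_range[2]),
    k_unspliced = k_unspliced, k_intron = k_intron, r_post = r_post,
    p_allnone = p_allnone, q_spliced = q_spliced)

  intr <- fs$introns[order(tx_id, intron_rank)]
  s_tab <- data.table(tx_id = intr$tx_id, intron_rank = intr$intron_rank,
                      intron_id = intr$intron_id)
  if (length(s_beta) == 1L) {
    s_tab[, s := as.numeric(s_beta)]
  } else {
    s_tab[, s := rbeta(.N, s_beta[1], s_beta[2])]
  }

  tx <- fs$transcripts[order(gene_id, tx_id)]
  iso <- tx[, .(tx_id, gene_id)]
  iso[, n_iso := .N, by = gene_id]
  iso[, prop := 1.0]
  two <- iso[n_iso == 2L]
  if (nrow(two) > 0L) {
    major <- if (is.null(isoform_props)) {
      rbeta(length(unique(two$gene_id)), 6, 3)
    } else rep(isoform_props[1], length(unique(two$gene_id)))
    mj <- data.table(gene_id = unique(two$gene_id), pmaj = major)
    iso <- merge(iso, mj, by = "gene_id", all.x = TRUE)
    iso[n_iso == 2L, prop := {
      p <- pmaj[1L]
      c(p, 1 - p)[order(order(tx_id))]
    }, by = gene_id]
    iso[, pmaj := NULL]
  }
  iso <- merge(iso, genes[, .(gene_id, k_early, k_late)], by = "gene_id")
  setnames(iso, c("k_early", "k_late"), c("k_early_iso", "k_late_iso"))
  if (identical(isoform_k_late, "flip")) {
    # isoform-specific late decay: major isoform destabilized, minor
    # stabilized, so dominance can flip between 0h and 6h
    iso[n_iso == 2L, k_late_iso := ifelse(prop >= 0.5, 1.2, 0.02)]
  }

  regions <- list()
  if (nrow(fs$prompts) > 0L) {
    regions$prompt <- fs$prompts[, .(region_id = paste0("PROMPT_", gene_id),
                                     class = "prompt", chrom, strand, start, end)]
  }
  if (nrow(fs$readthrough) > 0L) {
    regions$readthrough <- fs$readthrough[, .(
      region_id = paste0("RT_", gene_id), class = "readthrough",
      chrom, strand, start, end)]
  }
  if (!is.null(fs$enhancers) && nrow(fs$enhancers) > 0L) {
    regions$eRNA <- fs$enhancers[, .(region_id = paste0("ERNA_", family),
                                     class = "eRNA", chrom, strand, start, end)]
  }
  class_regions <- rbindlist(regions)
  if (class_level_mean <= 0) {
    class_regions <- class_regions[0L]
  }
  if (nrow(class_regions) > 0L) {
    class_regions[, level := rlnorm(.N, log(class_level_mean), 0.5)]
    class_regions[, k := class_rates[class]]
  }

  structure(list(fs = fs, genes = genes, s = s_tab, isoforms = iso,
                 class_regions = class_regions, seed = seed),
            class = "sim_truth")
}

#' Override per-gene decay rates in a simulated truth
#'
#' Sets mature decay rates for selected genes in both the gene table and
#' the derived per-isoform table (isoforms inherit their gene's rates
#' unless flipped). Used to state mixed worlds, e.g. a decaying test set
#' against a long-lived background.
#'
#' @param truth a \code{\link{sim_params}} object.
#' @param gene_ids genes to modify.
#' @param k_early,k_late new rates per hour (recycled).
#' @return the modified \code{sim_truth}.
#' @export
set_gene_rates <- function(truth, gene_ids, k_early, k_late = k_early) {
  stopifnot(inherits(truth, "sim_truth"),
            all(gene_ids %in% truth$genes$gene_id))
  upd <- data.table(gene_id = gene_ids, ke = k_early, kl = k_late)
  truth$genes[upd, on = "gene_id", `:=`(k_early = i.ke, k_late = i.kl)]
  truth$isoforms[upd, on = "gene_id",
                 `:=`(k_early_iso = i.ke, k_late_iso = i.kl)]
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes (%d isoforms), %d introns, %d class regions, seed %d\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$s),
              if (is.null(x$class_regions)) 0L else nrow(x$class_regions),
              x$seed))
  invisible(x)
}

# survival of a mature molecule from birth to t under biphasic decay
.survive_mature <- function(t, k_early, k_late, t_break = 2) {
  ifelse(t <= t_break, exp(-k_early * t),
         exp(-k_early * t_break - k_late * (t - t_break)))
}

# probability an unspliced-born molecule has converted to mature by t and
# survived: integrate conversion time tau ~ competing Exp(r_post) against
# death Exp(k_unspliced), then biphasic mature survival from tau to t
.convert_mature <- function(t, k_unspliced, r_post, k_early,
                            k_late = k_early, t_break = 2) {
  if (r_post <= 0) return(rep(0, length(t)))
  ku <- k_unspliced + r_post
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= 0) { out[i] <- 0; next }
    if (ti <= t_break) {
      out[i] <- r_post * exp(-k_early * ti) * .exp_int(ku - k_early, 0, ti)
    } else {
      early_part <- r_post * exp(-k_early * t_break - k_late * (ti - t_break)) *
        .exp_int(ku - k_early, 0, t_break)
      late_part <- r_post * exp(-k_late * ti) *
        .exp_int(ku - k_late, t_break, ti)
      out[i] <- early_part + late_part
    }
  }
  out
}

#' Expected molecule count of an RNA species under first-order kinetics
#'
#' Closed-form expectations for the generative model: mature RNA decays
#' with a biphasic rate (k_early before \code{t_break}, k_late after);
#' unspliced RNA is lost both to decay (k_unspliced) and to conversion into
#' the mature pool (r_post); \code{species = "converted"} gives the
#' unspliced-born molecules that have converted and still survive at t
#' (the two-compartment closed form); excised introns decay with k_intron.
#'
#' @param species one of "mature", "unspliced", "converted",
#'   "excised_intron".
#' @param t chase time in hours (vectorized).
#' @param n0 expected molecules of the species' birth pool at t = 0.
#' @param k_early,k_late mature decay rates per hour (late defaults to
#'   early, i.e. monophasic).
#' @param k_unspliced,k_intron,r_post see \code{\link{sim_params}}.
#' @param t_break hour at which the mature rate switches (default 2).
#' @return expected molecule count(s).
#' @export
expected_abundance <- function(species = c("mature", "unspliced",
                                           "converted", "excised_intron"),
                               t, n0, k_early = 0, k_late = k_early,
                               k_unspliced = 0, k_intron = 0, r_post = 0,
                               t_break = 2) {
  species <- match.arg(species)
  rates <- c(k_early, k_late, k_unspliced, k_intron, r_post)
  if (any(rates < 0)) stop("decay/conversion rates must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  switch(species,
    mature = n0 * .survive_mature(t, k_early, k_late, t_break),
    unspliced = n0 * exp(-(k_unspliced + r_post) * t),
    converted = n0 * .convert_mature(t, k_unspliced, r_post, k_early,
                                     k_late, t_break),
    excised_intron = n0 * exp(-k_intron * t))
}

# splice-state pattern table for one transcript: all realized birth states
# with their probabilities. Patterns are strings over introns in 5'->3'
# rank order ("1" = spliced).
.pattern_probs <- function(m, p_allnone, q_spliced, s) {
  if (m == 0L) {
    return(data.table(pattern = "", p_born = 1.0))
  }
  all1 <- paste(rep("1", m), collapse = "")
  all0 <- paste(rep("0", m), collapse = "")
  pats <- data.table(pattern = c(all1, all0),
                     p_born = c(p_allnone * q_spliced,
                                p_allnone * (1 - q_spliced)))
  if (p_allnone < 1) {
    if (m > 14L) stop("independent splicing mode limited to 14 introns")
    grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
    pp <- apply(grid, 1L, function(b) prod(ifelse(b == 1L, s, 1 - s)))
    ind <- data.table(pattern = apply(grid, 1L, paste, collapse = ""),
                      p_born = (1 - p_allnone) * pp)
    pats <- rbind(pats, ind)
    pats <- pats[, .(p_born = sum(p_born)), by = pattern]
  }
  pats[p_born > 0]
}

#' Expected molecule population at a chase timepoint
#'
#' Deterministic expectations per molecule class; the Poisson draws of
#' \code{\link{simulate_population}} are centered on these values.
#'
#' @param truth a \code{\link{sim_params}} object.
#' @param t chase time in hours.
#' @return data.table with columns \code{kind} ("tx", "intron", "class"),
#'   ids, splice \code{pattern} (5'->3' over introns, "1" = spliced) and
#'   \code{exp_count}.
#' @export
expected_population <- function(truth, t) {
  stopifnot(inherits(truth, "sim_truth"))
  fs <- truth$fs
  out <- vector("list", nrow(truth$isoforms) + 2L)
  j <- 0L
  for (i in seq_len(nrow(truth$isoforms))) {
    isoi <- truth$isoforms[i]
    gp <- truth$genes[gene_id == isoi$gene_id]
    sv <- truth$s[tx_id == isoi$tx_id][order(intron_rank), s]
    m <- length(sv)
    pats <- .pattern_probs(m, gp$p_allnone, gp$q_spliced, sv)
    n0 <- gp$synthesis_level * isoi$prop
    all1 <- paste(rep("1", m), collapse = "")
    full <- pats$pattern == all1
    p_full <- if (any(full)) pats$p_born[full] else 0
    p_rest <- pats$p_born[!full]
    exp_full <- n0 * p_full * .survive_mature(t, isoi$k_early_iso, isoi$k_late_iso) +
      n0 * sum(p_rest) * .convert_mature(t, gp$k_unspliced, gp$r_post,
                                         isoi$k_early_iso, isoi$k_late_iso)
    res <- data.table(kind = "tx", gene_id = isoi$gene_id,
                      tx_id = isoi$tx_id, pattern = all1,
                      intron_id = NA_character_, region_id = NA_character_,
                      exp_count = exp_full)
    if (length(p_rest) > 0L) {
      res <- rbind(res, data.table(
        kind = "tx", gene_id = isoi$gene_id, tx_id = isoi$tx_id,
        pattern = pats$pattern[!full], intron_id = NA_character_,
        region_id = NA_character_,
        exp_count = n0 * p_rest * exp(-(gp$k_unspliced + gp$r_post) * t)))
    }
    if (m > 0L) {
      p_spliced_birth <- gp$p_allnone * gp$q_spliced + (1 - gp$p_allnone) * sv
      st <- truth$s[tx_id == isoi$tx_id][order(intron_rank)]
      res <- rbind(res, data.table(
        kind = "intron", gene_id = isoi$gene_id, tx_id = isoi$tx_id,
        pattern = NA_character_, intron_id = st$intron_id,
        region_id = NA_character_,
        exp_count = n0 * p_spliced_birth * exp(-gp$k_intron * t)))
    }
    j <- j + 1L
    out[[j]] <- res
  }
  if (!is.null(truth$class_regions) && nrow(truth$class_regions) > 0L) {
    cr <- truth$class_regions
    j <- j + 1L
    out[[j]] <- data.table(kind = "class", gene_id = NA_character_,
                           tx_id = NA_character_, pattern = NA_character_,
                           intron_id = NA_character_,
                           region_id = cr$region_id,
                           exp_count = cr$level * exp(-cr$k * t))
  }
  rbindlist(out[seq_len(j)])
}

#' Draw the molecule population at a chase timepoint
#'
#' Poisson molecule counts around \code{\link{expected_population}}; the
#' splice state of each molecule was drawn once at synthesis, so a class is
#' (transcript, splice pattern), an excised intron, or a non-genic region.
#'
#' @param truth a \code{\link{sim_params}} object.
#' @param t chase time in hours.
#' @param seed RNG seed.
#' @return the expectation table with an added integer \code{count}.
#' @export
simulate_population <- function(truth, t, seed) {
  pop <- expected_population(truth, t)
  set.seed(derive_seed(seed, sprintf("pop_t%g", t)))
  pop[, count := rpois(.N, exp_count)]
  pop[count > 0L]
}

# genomic segment map of one molecule class (molecule coordinates are
# genomic-left order; fragment placement is strand-symmetric so this loses
# nothing). Returns data.table(m_start, m_end, g_start).
.segment_map <- function(exons, introns_retained) {
  seg <- rbind(exons[, .(start, end)], introns_retained[, .(start, end)])
  setorder(seg, start)
  # merge touching segments (exon|retained-intron|exon runs are contiguous)
  grp <- cumsum(c(1L, as.integer(seg$start[-1L] > seg$end[-nrow(seg)])))
  seg <- seg[, .(start = min(start), end = max(end)), by = .(grp = grp)]
  w <- seg$end - seg$start
  data.table(m_start = cumsum(c(0L, head(w, -1L))),
             m_end = cumsum(w), g_start = seg$start)
}

#' Sample aligned paired-end fragments from a molecule population
#'
#' Fragment lengths are truncated-normal (default Normal(450, 25) clipped
#' to \[2 x read_len, molecule length\]); fragment starts are uniform along
#' the molecule; molecules attract fragments in proportion to their count
#' times the number of available start positions (length weighting), which
#' makes per-base coverage uniform across molecule classes. Transcript
#' coordinates are mapped through the splice state, so a spliced intron
#' yields a split alignment and a retained intron a contiguous block. Two
#' read_len mate blocks are reported; the insert between them is not
#' aligned. Fragments allocated to molecules shorter than 2 x read_len are
#' skipped and tallied (attribute \code{"skipped"}), so emitted + skipped
#' equals the requested depth in \code{"fixed"} mode.
#'
#' @param pop population table from \code{\link{simulate_population}}.
#' @param truth the \code{\link{sim_params}} object (for the annotation).
#' @param depth fragments to sample ("fixed" mode) or expected fragments
#'   per unit anchor weight (see \code{depth_mode}).
#' @param seed RNG seed.
#' @param read_len mate length in nt (default 150).
#' @param frag_mean,frag_sd fragment length distribution (default 450, 25;
#'   sequenced fragments were 400-500 bp).
#' @param depth_mode \code{"fixed"}: exactly \code{depth} fragments are
#'   allocated. \code{"anchored"}: per-class Poisson with a constant
#'   capture rate \code{depth / anchor_weight}, so library size tracks the
#'   surviving labeled RNA (a spike-in-anchored library); pass
#'   \code{anchor_weight} from \code{\link{anchor_weight}} at 0h.
#' @param anchor_weight normalizing weight for anchored mode.
#' @return a \code{\link{fragment_set}} with attribute \code{"skipped"}.
#' @export
sample_fragments <- function(pop, truth, depth, seed, read_len = 150L,
                             frag_mean = 450, frag_sd = 25,
                             depth_mode = c("fixed", "anchored"),
                             anchor_weight = NULL) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(inherits(truth, "sim_truth"), depth > 0)
  fs <- truth$fs
  set.seed(derive_seed(seed, "fragments"))

  pop <- copy(pop)[count > 0L]
  pop[, cls := .I]
  segs <- vector("list", nrow(pop))
  meta <- vector("list", nrow(pop))
  intr_all <- fs$introns
  ex_all <- fs$exons
  cr <- truth$class_regions
  for (i in seq_len(nrow(pop))) {
    row <- pop[i]
    if (row$kind == "tx") {
      ex <- ex_all[tx_id == row$tx_id]
      intr <- intr_all[tx_id == row$tx_id]
      if (nrow(intr) > 0L) {
        spliced <- strsplit(row$pattern, "")[[1]] == "1"
        retained <- intr[!spliced[intron_rank]]
      } else retained <- intr
      sm <- .segment_map(ex, retained)
      strand <- ex$strand[1L]; chrom <- ex$chrom[1L]
    } else if (row$kind == "intron") {
      it <- intr_all[intron_id == row$intron_id]
      sm <- data.table(m_start = 0L, m_end = it$end - it$start,
                       g_start = it$start)
      strand <- it$strand; chrom <- it$chrom
    } else {
      rg <- cr[region_id == row$region_id]
      sm <- data.table(m_start = 0L, m_end = rg$end - rg$start,
                       g_start = rg$start)
      strand <- rg$strand; chrom <- rg$chrom
    }
    sm[, cls := i]
    segs[[i]] <- sm
    meta[[i]] <- data.table(cls = i, chrom = chrom, strand = strand,
                            mol_len = sm[.N, m_end])
  }
  segs <- rbindlist(segs)
  meta <- rbindlist(meta)
  pop <- merge(pop, meta, by = "cls")

  w <- pmax(pop$mol_len - frag_mean + 1, 1) * pop$count
  if (depth_mode == "fixed") {
    nfrag <- as.vector(rmultinom(1L, size = as.integer(depth), prob = w))
  } else {
    if (is.null(anchor_weight)) stop("anchored mode needs anchor_weight")
    nfrag <- rpois(length(w), depth * w / anchor_weight)
  }
  pop[, nfrag := nfrag]

  short <- pop$mol_len < 2L * read_len
  skipped <- sum(pop$nfrag[short])
  pop_ok <- pop[!short & nfrag > 0L]
  if (nrow(pop_ok) == 0L) {
    empty <- fragment_set(
      data.table(frag_id = integer(), name = character(), chrom = character(),
                 strand = character(), mapq = integer()),
      data.table(frag_id = integer(), mate = integer(), start = integer(),
                 end = integer()))
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  fr <- pop_ok[rep(seq_len(.N), nfrag),
               .(cls, chrom, strand, mol_len)]
  n <- nrow(fr)
  fr[, frag_id := seq_len(n)]
  # truncated-normal fragment length within [2*read_len, mol_len]
  lo <- pnorm(2 * read_len, frag_mean, frag_sd)
  hi <- pnorm(fr$mol_len, frag_mean, frag_sd)
  u <- runif(n, lo, hi)
  fr[, L := as.integer(pmin(pmax(round(qnorm(u, frag_mean, frag_sd)),
                                 2L * read_len), mol_len))]
  fr[, s := as.integer(floor(runif(n) * (mol_len - L + 1L)))]

  mates <- rbind(
    fr[, .(frag_id, cls, mate = 1L, a = s, b = s + read_len)],
    fr[, .(frag_id, cls, mate = 2L, a = s + L - read_len, b = s + L)])
  blocks <- segs[mates, on = .(cls, m_start < b, m_end > a),
                 .(frag_id = i.frag_id, mate = i.mate,
                   start = g_start + pmax(i.a - x.m_start, 0L),
                   end = g_start + pmin(i.b, x.m_end) - x.m_start),
                 allow.cartesian = TRUE]
  frags <- fr[, .(frag_id, name = sprintf("f%07d", frag_id),
                  chrom, strand, mapq = 255L)]
  out <- fragment_set(frags, blocks)
  attr(out, "skipped") <- skipped
  out
}

#' Total fragment-attraction weight of the expected population
#'
#' Used to calibrate the capture rate of anchored-depth sampling:
#' \code{depth / anchor_weight(truth, 0, ...)} fragments per unit weight
#' keeps the expected library size of the 0h sample at \code{depth} and
#' lets later libraries shrink with the surviving RNA.
#'
#' @inheritParams sample_fragments
#' @param t chase time in hours.
#' @return numeric scalar.
#' @export
anchor_weight <- function(truth, t = 0, frag_mean = 450) {
  pop <- expected_population(truth, t)
  len <- .molecule_lengths(pop, truth)
  sum(pmax(len - frag_mean + 1, 1) * pop$exp_count)
}

# molecule length per population row (no segment maps needed)
.molecule_lengths <- function(pop, truth) {
  fs <- truth$fs
  exlen <- fs$exons[, .(elen = sum(end - start)), by = tx_id]
  inlen <- fs$introns[, .(tx_id, intron_rank, intron_id, ilen = end - start)]
  out <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    row <- pop[i]
    if (row$kind == "tx") {
      base <- exlen[tx_id == row$tx_id, elen]
      il <- inlen[tx_id == row$tx_id][order(intron_rank), ilen]
      if (length(il) > 0L) {
        retained <- strsplit(row$pattern, "")[[1]] == "0"
        base <- base + sum(il[retained])
      }
      out[i] <- base
    } else if (row$kind == "intron") {
      out[i] <- inlen[intron_id == row$intron_id, ilen]
    } else {
      rg <- truth$class_regions[region_id == row$region_id]
      out[i] <- rg$end - rg$start
    }
  }
  out
}

#' Simulate a full labeling/chase experiment
#'
#' Draws one shared annotation and ground truth, then per (cell line,
#' timepoint, replicate) an independent molecule population and fragment
#' sample. Cell lines share parameters and differ only in sampling noise.
#'
#' @param n_genes,n_two_isoform,seed passed to \code{\link{sim_annotation}}
#'   / \code{\link{sim_params}}.
#' @param timepoints chase times in hours (default c(0, 2, 6)).
#' @param replicates replicates per timepoint (default 2, two independent
#'   growths).
#' @param cell_lines character vector of cell line labels.
#' @param depth fragments per sample.
#' @param depth_mode see \code{\link{sample_fragments}}.
#' @param params_args list of extra arguments for \code{\link{sim_params}}.
#' @param annotation_args list of extra arguments for
#'   \code{\link{sim_annotation}}.
#' @param read_len,frag_mean,frag_sd fragment geometry.
#' @return list with \code{truth}, \code{fs}, \code{samples} (named list of
#'   fragment_sets) and \code{sample_sheet} (data.table of metadata).
#' @export
simulate_experiment <- function(n_genes = 30L, n_two_isoform = 6L, seed = 1L,
                                timepoints = c(0, 2, 6), replicates = 2L,
                                cell_lines = "CL1", depth = 20000L,
                                depth_mode = "fixed",
                                params_args = list(),
                                annotation_args = list(),
                                read_len = 150L, frag_mean = 450,
                                frag_sd = 25) {
  fs <- do.call(sim_annotation, c(list(n_genes = n_genes,
                                       n_two_isoform = n_two_isoform,
                                       seed = seed), annotation_args))
  truth <- do.call(sim_params, c(list(fs = fs, seed = seed), params_args))
  aw <- if (depth_mode == "anchored") anchor_weight(truth, 0, frag_mean) else NULL
  sheet <- CJ(cell_line = cell_lines, timepoint = timepoints,
              replicate = seq_len(replicates), sorted = FALSE)
  sheet[, sample := sprintf("%s_%gh_r%d", cell_line, timepoint, replicate)]
  samples <- vector("list", nrow(sheet))
  names(samples) <- sheet$sample
  for (i in seq_len(nrow(sheet))) {
    si <- sheet[i]
    sseed <- derive_seed(seed, si$sample)
    pop <- simulate_population(truth, si$timepoint, sseed)
    samples[[i]] <- sample_fragments(pop, truth, depth,
                                     seed = derive_seed(sseed, "frag"),
                                     read_len = read_len,
                                     frag_mean = frag_mean,
                                     frag_sd = frag_sd,
                                     depth_mode = depth_mode,
                                     anchor_weight = aw)
  }
  list(truth = truth, fs = fs, samples = samples, sample_sheet = sheet)
}

#' Write a simulated experiment to disk
#'
#' Emits the annotation as GTF, one coordinate-sorted SAM per sample, the
#' ground truth as JSON and a sample sheet TSV; files round-trip through
#' \code{\link{load_annotation}} / \code{\link{read_sam}} /
#' \code{\link{read_truth}}.
#'
#' @param sim result of \code{\link{simulate_experiment}}.
#' @param outdir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(outdir, "annotation.gtf"),
             truth = file.path(outdir, "truth.json"),
             sample_sheet = file.path(outdir, "sample_sheet.tsv"))
  write_annotation(sim$fs, paths[["annotation"]])
  write_truth(sim$truth, paths[["truth"]])
  sheet <- copy(sim$sample_sheet)
  sheet[, path := paste0(sample, ".sam")]  # relative to outdir
  maxend <- max(sim$fs$genes$end) + 60000L
  cl <- setNames(maxend, sim$fs$genes$chrom[1L])
  for (i in seq_len(nrow(sheet))) {
    write_sam(sim$samples[[sheet$sample[i]]],
              file.path(outdir, sheet$path[i]), chrom_lengths = cl)
  }
  write_tsv(sheet, paths[["sample_sheet"]])
  invisible(c(paths, setNames(sheet$path, sheet$sample)))
}

#' @rdname write_simulation
#' @param truth a \code{\link{sim_params}} object.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(seed = truth$seed, genes = truth$genes, s = truth$s,
              isoforms = truth$isoforms,
              class_regions = truth$class_regions)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation
#' @return \code{read_truth}: the ground-truth tables (without the
#'   annotation, which lives in the GTF).
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(seed = obj$seed, genes = as.data.table(obj$genes),
              s = as.data.table(obj$s),
              isoforms = as.data.table(obj$isoforms),
              class_regions = if (length(obj$class_regions))
                as.data.table(obj$class_regions) else NULL)
  out
}

#' Simulate repeat-family alignment hits including multimappers
#'
#' Repeat-derived fragments align to one repeat family or, for a fraction
#' of them, ambiguously to two; this emulates the multimapper input of
#' fractional repeat counting (a fragment hitting n families contributes
#' 1/n to each).
#'
#' @param n fragments.
#' @param families character vector of family names.
#' @param p_multi probability a fragment hits two families.
#' @param seed RNG seed.
#' @return data.table(frag_id, family), one row per reported alignment.
#' @export
sim_repeat_hits <- function(n, families, p_multi = 0.4, seed = 1L) {
  set.seed(derive_seed(seed, "repeat_hits"))
  fam1 <- sample(families, n, replace = TRUE)
  multi <- runif(n) < p_multi & length(families) > 1L
  hits <- data.table(frag_id = seq_len(n), family = fam1)
  if (any(multi)) {
    second <- vapply(fam1[multi], function(f)
      sample(setdiff(families, f), 1L), character(1))
    hits <- rbind(hits, data.table(frag_id = which(multi), family = second))
  }
  setorder(hits, frag_id, family)
  hits[]
}
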