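# tiny_fs(): G1 on + with exons [1000,1500) [2000,2500) [3000,3500),
# G2 on - with exons [20000,20800) [22000,22600)

test_that("fragments are classified into the six RNA classes", {
  fs <- tiny_fs()
  fset <- make_fset(list(
    list(strand = "+", blocks = list(c(1, 1100, 1250), c(2, 1300, 1450))),  # exon
    list(strand = "+", blocks = list(c(1, 1600, 1750), c(2, 1800, 1950))),  # intron
    list(strand = "+", blocks = list(c(1, 1400, 1550), c(2, 1600, 1750))),  # exon+intron -> exon
    list(strand = "+", blocks = list(c(1, 20100, 20250), c(2, 20300, 20450))),  # antisense exonic
    list(strand = "+", blocks = list(c(1, 21000, 21150), c(2, 21200, 21350))),  # antisense intronic
    list(strand = "+", blocks = list(c(1, 8000, 8150), c(2, 8200, 8350))),  # intergenic
    list(strand = "+", blocks = list(c(1, 1100, 1250), c(2, 1300, 1450)),
         mapq = 10)))                                                       # below mapq_min
  cls <- classify_fragments(fset, fs)
  expect_equal(cls$class,
               c("exon", "intron", "exon", "exon_antisense",
                 "intron_antisense", "intergenic"))
  expect_equal(attr(cls, "mapq_excluded"), 1L)
})

test_that("fragments touching two sense-strand genes are ambiguous", {
  ex <- data.table::data.table(
    gene_id = c("A", "B"), tx_id = c("A.t", "B.t"), chrom = "chrT",
    strand = "+", start = c(1000L, 1400L), end = c(1300L, 1700L))
  fs <- suppressWarnings(feature_set(ex))  # overlapping genes, tight layout
  fset <- make_fset(list(
    list(strand = "+", blocks = list(c(1, 1100, 1250), c(2, 1450, 1600)))))
  expect_equal(classify_fragments(fset, fs)$class, "ambiguous")
})

test_that("fractional counts split fragment mass per aligned base", {
  feats <- data.table::data.table(
    feature_id = c("F1", "F2"), chrom = "chrT", strand = "+",
    start = c(1000L, 1150L), end = c(1150L, 2000L))
  # 300 aligned bases, 180 inside F2 -> 0.6; 120 in F1 -> 0.4
  fset <- make_fset(list(
    list(strand = "+", blocks = list(c(1, 1030, 1180), c(2, 1180, 1330)))))
  fc <- fractional_counts(fset, feats, mapq_min = 0)
  expect_equal(fc[feature_id == "F2", count], 0.6)
  expect_equal(fc[feature_id == "F1", count], 0.4)
  expect_equal(sum(fc$count), 1)  # partition conservation

  # fully inside one feature -> 1.0; opposite strand -> 0
  fset2 <- make_fset(list(
    list(strand = "+", blocks = list(c(1, 1200, 1350), c(2, 1400, 1550))),
    list(strand = "-", blocks = list(c(1, 1200, 1350), c(2, 1400, 1550)))))
  fc2 <- fractional_counts(fset2, feats, mapq_min = 0)
  expect_equal(fc2[feature_id == "F2", count], 1.0)
})

test_that("repeat fractional counting follows the 1/n multimapper rule", {
  hits <- data.table::data.table(
    frag_id = c(1L, 2L, 2L, 3L),
    family = c("L1", "L1", "Alu", "Alu"))
  rc <- repeat_fractional_counts(hits)
  expect_equal(rc[family == "L1", count], 1.5)
  expect_equal(rc[family == "Alu", count], 1.5)

  # closed-form total on simulated multimapper hits: with fraction p2
  # hitting two families, total mass still equals the fragment count
  sim <- sim_repeat_hits(1000, c("L1", "Alu", "LTR"), p_multi = 0.4,
                         seed = 42)
  rc2 <- repeat_fractional_counts(sim)
  expect_equal(sum(rc2$count), 1000)
  n2 <- sim[, .N, by = frag_id][N == 2L, .N]
  expect_lt(abs(n2 / 1000 - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
})

test_that("class profiles are normalized and reject empty samples", {
  fs <- tiny_fs()
  all_exonic <- make_fset(list(
    list(strand = "+", blocks = list(c(1, 1050, 1200), c(2, 1250, 1400))),
    list(strand = "-", blocks = list(c(1, 22100, 22250), c(2, 22300, 22450)))))
  cp <- class_profile(all_exonic, fs)
  expect_equal(cp[cp$class == "exon", ]$fraction, 1.0)
  expect_equal(sum(cp$fraction), 1.0)

  low <- make_fset(list(
    list(strand = "+", mapq = 1, blocks = list(c(1, 1050, 1200), c(2, 1250, 1400)))))
  expect_error(class_profile(low, fs), "empty sample")
})

test_that("relative class stability is the exon-normalized double ratio", {
  mk_prof <- function(exon, intron) {
    data.table::data.table(
      class = c("exon", "intron", "exon_antisense", "intron_antisense",
                "intergenic", "ambiguous"),
      count = 0L, fraction = c(exon, intron, 0, 0, 1 - exon - intron, 0))
  }
  p0 <- mk_prof(0.10, 0.75)
  p2 <- mk_prof(0.20, 0.35)
  expect_equal(relative_class_stability(p0, p2, "intron"),
               (0.35 / 0.75) / (0.20 / 0.10), tolerance = 1e-12)
  expect_equal(round(relative_class_stability(p0, p2, "intron"), 4), 0.2333)
  # a class tracking exons exactly has relative stability 1
  expect_equal(relative_class_stability(p0, p0, "intron"), 1.0)
  expect_equal(relative_class_stability(p0, p2, "exon"), 1.0)
})

test_that("simulated class stabilities track exp(-(k_class - k_exon) t)", {
  fs <- sim_annotation(n_genes = 10, n_two_isoform = 0, seed = 21,
                       n_enhancers = 6, n_repeats = 0)
  # mature-only genes with slow decay; all non-genic classes share one
  # fast rate, so the intergenic class (PROMPT/eRNA/readthrough regions)
  # has a closed-form relative stability exp(-(k_class - k_exon) t)
  k_mat <- 0.05
  k_cls <- 1.0
  tr <- sim_params(fs, seed = 21, p_allnone = 1, q_spliced = 1,
                   k_early_range = c(k_mat, k_mat),
                   k_late_range = c(k_mat, k_mat),
                   synthesis_mean = 300,
                   class_rates = c(prompt = k_cls, eRNA = k_cls,
                                   readthrough = k_cls))
  prof <- lapply(c(0, 2, 6), function(t) {
    pop <- simulate_population(tr, t, seed = 31)
    fset <- sample_fragments(pop, tr, depth = 60000, seed = 31 + t,
                             depth_mode = "anchored",
                             anchor_weight = anchor_weight(tr, 0))
    class_profile(fset, fs)
  })
  rel2 <- relative_class_stability(prof[[1]], prof[[2]], "intergenic")
  rel6 <- relative_class_stability(prof[[1]], prof[[3]], "intergenic")
  expect_lt(rel2, 1)
  expect_lt(rel6, rel2)
  expect_equal(rel2, exp(-(k_cls - k_mat) * 2), tolerance = 0.15)
  expect_equal(rel6, exp(-(k_cls - k_mat) * 6), tolerance = 0.3)
})
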