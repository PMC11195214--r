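test_that("GTF loading derives introns and groups transcripts", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tsrc\texon\t500\t600\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\tsrc\texon\t5000\t5600\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";'),
    gtf)
  fs <- suppressWarnings(load_annotation(gtf))  # fixture sits near chrom start

  # 1-based closed exons 100-200/300-400/500-600 are 0-based half-open
  # [99,200), [299,400), [499,600); introns are the gaps
  t1_introns <- fs$introns[tx_id == "gA.t1"][order(start)]
  expect_equal(t1_introns$start, c(200L, 400L))
  expect_equal(t1_introns$end, c(299L, 499L))

  # single-exon transcripts have zero introns
  expect_equal(nrow(fs$introns[tx_id %in% c("gA.t2", "gB.t1")]), 0L)

  # transcripts sharing gene_id collapse into one gene model
  expect_equal(fs$genes[gene_id == "gA", n_tx], 2L)
  expect_equal(nrow(fs$genes), 2L)
})

test_that("malformed GTF lines and overlapping exons are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\tbroken line"), bad)
  expect_error(load_annotation(bad), "line 2")

  ex <- data.table::data.table(
    gene_id = "g", tx_id = "t", chrom = "c", strand = "+",
    start = c(0L, 50L), end = c(100L, 150L))
  expect_error(feature_set(ex), "overlapping exons")
})

test_that("PROMPT windows sit antisense upstream of the TSS", {
  g <- data.table::data.table(gene_id = c("P", "M"), chrom = "c",
                              strand = c("+", "-"),
                              start = c(10000L, 5000L),
                              end = c(15000L, 10000L), n_tx = 1L)
  pr <- derive_prompts(g, 4000L)
  expect_equal(pr[gene_id == "P", .(strand, start, end)],
               data.table::data.table(strand = "-", start = 6000L,
                                      end = 10000L))
  # minus-strand gene: TSS is the right edge, window continues rightwards
  expect_equal(pr[gene_id == "M", .(strand, start, end)],
               data.table::data.table(strand = "+", start = 10000L,
                                      end = 14000L))

  close_g <- data.table::data.table(gene_id = "x", chrom = "c",
                                    strand = "+", start = 1000L,
                                    end = 3000L, n_tx = 1L)
  expect_warning(trunc <- derive_prompts(close_g, 4000L), "truncated")
  expect_equal(trunc[, c(start, end)], c(0L, 1000L))
})

test_that("readthrough windows extend sense-downstream and clip at neighbors", {
  g <- data.table::data.table(
    gene_id = c("A", "B", "C"), chrom = "c", strand = c("+", "+", "-"),
    start = c(10000L, 25000L, 50000L), end = c(20000L, 26000L, 60000L),
    n_tx = 1L)
  rt <- derive_readthroughs(g, 10000L)
  # clipped at same-strand neighbor B starting at 25000
  expect_equal(rt[gene_id == "A", c(start, end, strand)],
               c("20000", "25000", "+"))
  # minus-strand gene extends leftwards
  expect_equal(rt[gene_id == "C", c(start, end, strand)],
               c("40000", "50000", "-"))
})

test_that("single-isoform multi-intron selection follows both rules", {
  ex <- data.table::rbindlist(list(
    # 1 transcript, 5 introns -> selected
    data.table::data.table(gene_id = "s5", tx_id = "s5.t", chrom = "c",
                           strand = "+", start = seq(0L, 5000L, 1000L),
                           end = seq(0L, 5000L, 1000L) + 200L),
    # 2 transcripts -> excluded
    data.table::data.table(gene_id = "m", tx_id = c("m.a", "m.a", "m.b"),
                           chrom = "c", strand = "+",
                           start = c(10000L, 12000L, 10000L),
                           end = c(10200L, 12200L, 10200L)),
    # 1 transcript, 1 intron -> excluded at min_introns = 2
    data.table::data.table(gene_id = "s1", tx_id = "s1.t", chrom = "c",
                           strand = "+", start = c(20000L, 22000L),
                           end = c(20300L, 22300L))))
  fs <- suppressWarnings(feature_set(ex))  # fixture sits near chrom start
  expect_equal(select_single_isoform_multi_intron(fs, 2L), "s5")
  expect_setequal(select_single_isoform_multi_intron(fs, 1L), c("s5", "s1"))
})

test_that("feature_set invariants: contiguity, round-trip, region disjointness", {
  fs <- sim_annotation(n_genes = 8, n_two_isoform = 2, seed = 7)

  # exons + introns tile the transcript span contiguously
  for (tx in fs$transcripts$tx_id) {
    parts <- rbind(fs$exons[tx_id == tx, .(start, end)],
                   fs$introns[tx_id == tx, .(start, end)])
    data.table::setorder(parts, start)
    expect_true(all(parts$start[-1L] == parts$end[-nrow(parts)]))
    expect_equal(c(parts$start[1L], parts$end[nrow(parts)]),
                 fs$transcripts[tx_id == tx, c(start, end)])
  }

  # GTF round trip preserves every interval
  gtf <- tempfile(fileext = ".gtf")
  write_annotation(fs, gtf)
  fs2 <- load_annotation(gtf)
  cols <- c("gene_id", "tx_id", "chrom", "strand", "start", "end")
  orig <- data.table::setorderv(fs$exons[, ..cols], cols)
  back <- data.table::setorderv(fs2$exons[, ..cols], cols)
  expect_equal(back, orig)

  # PROMPT / readthrough never overlap their own gene body on the same strand
  for (tab in list(fs$prompts, fs$readthrough)) {
    m <- merge(tab, fs$genes, by = "gene_id", suffixes = c("", ".g"))
    same <- m[strand == strand.g]
    if (nrow(same) > 0L) {
      expect_true(all(same$end <= same$start.g | same$start >= same$end.g))
    }
  }
})
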