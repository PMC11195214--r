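test_that("expected_abundance matches first-order closed forms", {
  k <- log(2) / 2  # 2h half-life
  expect_equal(expected_abundance("mature", 2, 1000, k_early = k), 500)
  expect_equal(log2(expected_abundance("mature", 2, 1000, k_early = k) / 1000),
               -1)
  # biphasic: further late-phase decay from 2h to 6h
  expect_equal(expected_abundance("mature", 6, 1000, k_early = k,
                                  k_late = log(2) / 4),
               1000 * exp(-2 * k - 4 * log(2) / 4))
  # all rates zero: conservation
  for (sp in c("mature", "unspliced", "excised_intron")) {
    expect_equal(expected_abundance(sp, c(0, 2, 6), 123), rep(123, 3))
  }
  expect_error(expected_abundance("mature", 2, 10, k_early = -1), ">= 0")
})

test_that("unspliced-to-mature conversion matches an ODE oracle", {
  # simplest conversion case: no unspliced decay, conversion at ln2/2 per hour
  u <- expected_abundance("unspliced", 2, 800, r_post = log(2) / 2)
  conv <- expected_abundance("converted", 2, 800, r_post = log(2) / 2)
  expect_equal(u, 400)
  expect_equal(conv, 400, tolerance = 1e-9)

  # general biphasic case against RK4 integration
  cases <- list(
    list(ku = 0.8, r = 0.4, ke = 0.3, kl = 0.9, t = 6),
    list(ku = 1.5, r = 0.1, ke = 0.05, kl = 0.05, t = 2),
    list(ku = 0.0, r = 0.7, ke = 0.6, kl = 0.1, t = 6),
    list(ku = 0.4, r = 0.4, ke = 0.4, kl = 0.4, t = 6))  # degenerate rates
  for (cs in cases) {
    ode <- ode_conversion(cs$t, 500, cs$ku, cs$r, cs$ke, cs$kl)
    expect_equal(expected_abundance("converted", cs$t, 500,
                                    k_early = cs$ke, k_late = cs$kl,
                                    k_unspliced = cs$ku, r_post = cs$r),
                 ode$mature_converted, tolerance = 1e-6)
    expect_equal(expected_abundance("unspliced", cs$t, 500,
                                    k_unspliced = cs$ku, r_post = cs$r),
                 ode$unspliced, tolerance = 1e-6)
  }
})

test_that("population draws follow the stated splice-state law", {
  fs <- sim_annotation(n_genes = 6, n_two_isoform = 0, seed = 2,
                       n_enhancers = 0, n_repeats = 0)
  # pure all-or-none, q = 0.7: fully spliced fraction ~ 0.7 at 0h
  tr <- sim_params(fs, seed = 2, p_allnone = 1, q_spliced = 0.7,
                   synthesis_mean = 2000, class_level_mean = 0)
  pop <- simulate_population(tr, 0, seed = 5)
  tx_pop <- pop[kind == "tx"]
  full <- vapply(seq_len(nrow(tx_pop)), function(i)
    !grepl("0", tx_pop$pattern[i]), logical(1))
  frac <- sum(tx_pop$count[full]) / sum(tx_pop$count)
  n <- sum(tx_pop$count)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  # all-or-none molecules are never partially spliced
  expect_true(all(full | !grepl("1", tx_pop$pattern)))

  # s_i = 0 with fast unspliced purge: unspliced pool empties by 6h
  tr2 <- sim_params(fs, seed = 2, p_allnone = 0, s_beta = 0,
                    k_unspliced = 3, r_post = 0, synthesis_mean = 500,
                    k_early_range = c(0.01, 0.01), class_level_mean = 0)
  pop6 <- simulate_population(tr2, 6, seed = 5)
  unspliced6 <- pop6[kind == "tx"][grepl("0", pattern), sum(count)]
  pop0 <- simulate_population(tr2, 0, seed = 5)
  unspliced0 <- pop0[kind == "tx"][grepl("0", pattern), sum(count)]
  expect_gt(unspliced0, 100)
  expect_lt(unspliced6 / unspliced0, 0.01)

  # determinism under a fixed seed
  expect_identical(simulate_population(tr, 2, seed = 9),
                   simulate_population(tr, 2, seed = 9))
})

test_that("fragment sampling maps splice states to alignment blocks", {
  fs <- sim_annotation(n_genes = 2, n_two_isoform = 0, seed = 4,
                       n_enhancers = 0, n_repeats = 0)
  tr <- sim_params(fs, seed = 4, class_level_mean = 0)
  tx <- fs$transcripts$tx_id[1L]
  g <- fs$transcripts$gene_id[1L]
  m <- nrow(fs$introns[tx_id == tx])
  mk_pop <- function(pattern) data.table::data.table(
    kind = "tx", gene_id = g, tx_id = tx, pattern = pattern,
    intron_id = NA_character_, region_id = NA_character_,
    exp_count = 50, count = 50L)

  # fully spliced: any multi-block mate must split exactly at an intron
  full <- sample_fragments(mk_pop(strrep("1", m)), tr, depth = 2000,
                           seed = 8)
  intr <- fs$introns[tx_id == tx]
  gaps <- full$blocks[, if (.N > 1)
    .(gs = end[-.N], ge = start[-1L]), by = .(frag_id, mate)]
  expect_gt(nrow(gaps), 0L)
  expect_true(all(paste(gaps$gs, gaps$ge) %in% paste(intr$start, intr$end)))

  # fully unspliced: alignment blocks never split
  none <- sample_fragments(mk_pop(strrep("0", m)), tr, depth = 2000,
                           seed = 8)
  n_blocks <- none$blocks[, .N, by = .(frag_id, mate)]
  expect_true(all(n_blocks$N == 1L))

  # fragment length distribution: mean within 450 +/- 5 at 10^4 draws
  frag_len <- function(fset) {
    sp <- fset$blocks[, .(mn = min(start), mx = max(end)), by = frag_id]
    sp$mx - sp$mn
  }
  big <- sample_fragments(mk_pop(strrep("0", m)), tr, depth = 10000,
                          seed = 9)
  expect_lt(abs(mean(frag_len(big)) - 450), 5)

  # depth conservation: emitted + skipped == requested
  expect_equal(length(big) + attr(big, "skipped"), 10000L)
})

test_that("simulation round-trips through GTF/SAM/JSON on disk", {
  sim <- simulate_experiment(n_genes = 4, n_two_isoform = 1, seed = 11,
                             depth = 600, replicates = 1L,
                             timepoints = c(0, 2))
  outdir <- file.path(tempdir(), "simrt")
  write_simulation(sim, outdir)

  fs2 <- load_annotation(file.path(outdir, "annotation.gtf"))
  expect_equal(data.table::setorder(fs2$exons[, .(tx_id, start, end)], tx_id, start),
               data.table::setorder(sim$fs$exons[, .(tx_id, start, end)], tx_id, start))

  sheet <- data.table::fread(file.path(outdir, "sample_sheet.tsv"))
  for (i in seq_len(nrow(sheet))) {
    fset0 <- sim$samples[[sheet$sample[i]]]
    fset1 <- read_sam(file.path(outdir, sheet$path[i]))
    expect_equal(length(fset1), length(fset0))
    # blocks and strands survive the round trip (ids are renumbered)
    b0 <- merge(fset0$blocks, fset0$frags[, .(frag_id, name, strand)],
                by = "frag_id")[order(name, mate, start),
                                .(name, mate, start, end, strand)]
    b1 <- merge(fset1$blocks, fset1$frags[, .(frag_id, name, strand)],
                by = "frag_id")[order(name, mate, start),
                                .(name, mate, start, end, strand)]
    expect_equal(b1, b0)
  }

  tru <- read_truth(file.path(outdir, "truth.json"))
  expect_equal(tru$genes$k_early, sim$truth$genes$k_early, tolerance = 1e-12)
  expect_equal(tru$isoforms$prop, sim$truth$isoforms$prop, tolerance = 1e-12)
})

test_that("flat kinetics give flat class fractions across timepoints", {
  fs <- sim_annotation(n_genes = 6, n_two_isoform = 0, seed = 13)
  tr <- sim_params(fs, seed = 13, p_allnone = 1, q_spliced = 0.5,
                   k_early_range = c(0, 0), k_late_range = c(0, 0),
                   k_unspliced = 0, k_intron = 0, r_post = 0,
                   synthesis_mean = 400,
                   class_rates = c(prompt = 0, eRNA = 0, readthrough = 0))
  profs <- lapply(c(0, 6), function(t) {
    pop <- simulate_population(tr, t, seed = 3)
    fset <- sample_fragments(pop, tr, depth = 30000, seed = 3 + t)
    class_profile(fset, fs)
  })
  expect_equal(profs[[2]]$fraction, profs[[1]]$fraction, tolerance = 0.02)
})
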