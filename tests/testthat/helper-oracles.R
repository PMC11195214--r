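# Test fixtures and independent oracles. The oracles deliberately use
# naive per-base / brute-force formulations so they share no code path
# with the package implementation.

library(data.table)

# -- fixture builders --------------------------------------------------------

# a deterministic 2-gene annotation: G1 (+, 3 exons) and G2 (-, 2 exons)
tiny_fs <- function() {
  ex <- data.table(
    gene_id = c("G1", "G1", "G1", "G2", "G2"),
    tx_id = c("G1.t1", "G1.t1", "G1.t1", "G2.t1", "G2.t1"),
    chrom = "chrT",
    strand = c("+", "+", "+", "-", "-"),
    start = c(1000L, 2000L, 3000L, 20000L, 22000L),
    end = c(1500L, 2500L, 3500L, 20800L, 22600L))
  suppressWarnings(feature_set(ex))  # G1's PROMPT window is truncated
}

# build a fragment_set from a compact spec:
# list of lists with fields chrom, strand, mapq (optional) and blocks =
# list of c(mate, start, end)
make_fset <- function(frag_specs) {
  frags <- rbindlist(lapply(seq_along(frag_specs), function(i) {
    sp <- frag_specs[[i]]
    data.table(frag_id = i, name = paste0("q", i),
               chrom = sp$chrom %||% "chrT",
               strand = sp$strand %||% "+",
               mapq = sp$mapq %||% 255L)
  }))
  blocks <- rbindlist(lapply(seq_along(frag_specs), function(i) {
    b <- do.call(rbind, frag_specs[[i]]$blocks)
    data.table(frag_id = i, mate = b[, 1], start = b[, 2], end = b[, 3])
  }))
  fragment_set(frags, blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- junction / pattern brute-force oracle -----------------------------------

# per-mate aligned base sets -> maximal covered runs
.oracle_runs <- function(starts, ends) {
  bases <- sort(unique(unlist(mapply(function(s, e) s:(e - 1L), starts, ends,
                                     SIMPLIFY = FALSE))))
  if (length(bases) == 0L) return(list())
  brk <- c(0L, which(diff(bases) != 1L), length(bases))
  lapply(seq_len(length(brk) - 1L), function(i)
    c(bases[brk[i] + 1L], bases[brk[i + 1L]] + 1L))  # [start, end)
}

# classify one fragment against one intron; returns subset of c("a","b","c")
oracle_junction <- function(fset, fid, intron, min_ov = 10L) {
  fr <- fset$frags[frag_id == fid]
  if (fr$chrom != intron$chrom || fr$strand != intron$strand) return(character())
  out <- character()
  for (m in 1:2) {
    b <- fset$blocks[frag_id == fid & mate == m]
    if (nrow(b) == 0L) next
    runs <- .oracle_runs(b$start, b$end)
    for (i in seq_along(runs)) {
      r <- runs[[i]]
      # contiguous crossing of the intron start / end boundary points
      if (r[1] <= intron$start - min_ov && r[2] >= intron$start + min_ov)
        out <- c(out, "b")
      if (r[1] <= intron$end - min_ov && r[2] >= intron$end + min_ov)
        out <- c(out, "c")
      # split: this run ends exactly at the intron start, the next run
      # starts exactly at the intron end, both flanks long enough
      if (i < length(runs)) {
        r2 <- runs[[i + 1L]]
        if (r[2] == intron$start && r2[1] == intron$end &&
            r[2] - r[1] >= min_ov && r2[2] - r2[1] >= min_ov)
          out <- c(out, "a")
      }
    }
  }
  sort(unique(out))
}

# exon-spanning pattern for one fragment ("SS"/"SU"/"US"/"UU"/"uninformative")
oracle_pattern <- function(fset, fid, up_intron, down_intron, min_ov = 10L) {
  st <- function(intron) {
    ev <- oracle_junction(fset, fid, intron, min_ov)
    spl <- "a" %in% ev
    uns <- any(c("b", "c") %in% ev)
    if (spl && !uns) "S" else if (uns && !spl) "U" else NA_character_
  }
  up <- st(up_intron)
  down <- st(down_intron)
  if (is.na(up) || is.na(down)) "uninformative" else paste0(up, down)
}

# -- kinetics oracle ---------------------------------------------------------

# RK4 integration of the unspliced -> mature two-compartment system with a
# piecewise mature decay rate
ode_conversion <- function(t_end, n0, k_unspliced, r_post, k_early,
                           k_late = k_early, t_break = 2, dt = 1e-4) {
  u <- n0; m <- 0
  step_phase <- function(u, m, t0, t1, k) {
    deriv <- function(u, m) c(-(k_unspliced + r_post) * u,
                              r_post * u - k * m)
    t <- t0
    while (t < t1 - 1e-12) {
      h <- min(dt, t1 - t)
      k1 <- deriv(u, m)
      k2 <- deriv(u + h / 2 * k1[1], m + h / 2 * k1[2])
      k3 <- deriv(u + h / 2 * k2[1], m + h / 2 * k2[2])
      k4 <- deriv(u + h * k3[1], m + h * k3[2])
      u <- u + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      m <- m + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      t <- t + h
    }
    c(u, m)
  }
  # integrate the two decay phases separately so the rate switch at
  # t_break never falls inside an RK4 step
  s <- step_phase(u, m, 0, min(t_end, t_break), k_early)
  if (t_end > t_break) s <- step_phase(s[1], s[2], t_break, t_end, k_late)
  list(unspliced = s[1], mature_converted = s[2])
}

# -- EM oracle ---------------------------------------------------------------

# grid-search maximum of the equivalence-class likelihood for 2 isoforms
grid_em_2iso <- function(classes, eff_len, n_grid = 10001L) {
  txs <- names(eff_len)
  members <- strsplit(classes$class, "|", fixed = TRUE)
  th1 <- seq(0, 1, length.out = n_grid)
  ll <- vapply(th1, function(p) {
    th <- setNames(c(p, 1 - p), txs)
    sum(classes$n * log(vapply(members, function(mm)
      sum(th[mm] / eff_len[mm]), numeric(1)) + 1e-300))
  }, numeric(1))
  th1[which.max(ll)]
}
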