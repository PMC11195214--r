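`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the run
#' seed plus a string tag, so that stages are reproducible independently and
#' adding a stage never perturbs the draws of another. Result is kept below
#' 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed integer base seed.
#' @param tag character scalar naming the stage/sample.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 13007 + 17) %% 2147483629)
}

# deterministic TSV writer (fixed eol, no scientific notation drift)
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", eol = "\n", quote = FALSE,
                     scipen = 50L)
  invisible(path)
}

# integral of exp(-lambda * tau) over [a, b], stable as lambda -> 0
.exp_int <- function(lambda, a, b) {
  small <- abs(lambda) < 1e-12
  out <- numeric(length(lambda))
  out[small] <- (b - a)
  l <- lambda[!small]
  out[!small] <- (exp(-l * a) - exp(-l * b)) / l
  out
}

# validate a 0-based half-open interval table
.check_intervals <- function(x, what = "interval") {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$start < 0L)) stop(what, ": negative start coordinate")
  if (any(x$end <= x$start)) stop(what, ": empty or inverted interval")
  if (!all(x$strand %in% c("+", "-"))) stop(what, ": strand must be + or -")
  invisible(x)
}

# overlap join between two 0-based half-open interval tables.
# Returns data.table(qid, sid, ov_start, ov_end) with row indices into
# query/subject. Both need columns chrom, start, end.
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.table(qid = integer(), sid = integer(),
                      ov_start = integer(), ov_end = integer()))
  }
  q <- data.table(chrom = query$chrom, s = query$start, e = query$end - 1L)
  s <- data.table(chrom = subject$chrom, s = subject$start,
                  e = subject$end - 1L, orig = seq_len(nrow(subject)))
  data.table::setkey(s, chrom, s, e)  # reorders s; yid indexes sorted rows
  hits <- data.table::foverlaps(q, s, type = "any", nomatch = NULL,
                                which = TRUE)
  out <- data.table(qid = hits$xid, sid = s$orig[hits$yid])
  out[, ov_start := pmax(query$start[qid], subject$start[sid])]
  out[, ov_end := pmin(query$end[qid], subject$end[sid])]
  out[]
}
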