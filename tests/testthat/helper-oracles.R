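# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (pure R string scans, direct hypergeometric
# enumeration, closed forms), so agreement is evidence, not tautology.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive pure-R Hamming scan; N mismatches everything. Small inputs only.
oracle_hamming_scan <- function(seqs, targets, max_mm, both_strands) {
  out <- list()
  for (r in seq_along(seqs)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seqs[r] else oracle_revcomp(seqs[r])
      qc <- strsplit(q, "")[[1]]
      L <- length(qc)
      for (t in seq_along(targets)) {
        if (strand == "-" && !both_strands[t]) next
        tc <- strsplit(targets[t], "")[[1]]
        if (L > length(tc)) next
        for (pos in 0:(length(tc) - L)) {
          w <- tc[pos + seq_len(L)]
          mm <- sum(w != qc | !(qc %in% c("A", "C", "G", "T")))
          if (mm <= max_mm) {
            out[[length(out) + 1L]] <- data.frame(
              read_idx = r, target_idx = t, start = pos, strand = strand,
              mismatches = mm)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_idx = integer(), target_idx = integer(),
                      start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# Best-stratum filtering + weights applied to an oracle hit table.
oracle_best_stratum <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  split_hits <- split(hits, hits$read_idx)
  do.call(rbind, lapply(split_hits, function(h) {
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    h$weight <- 1 / nrow(h)
    h
  }))
}

# Two-sided Fisher exact p by direct hypergeometric enumeration, summing all
# tables with point probability at most the observed (1e-7 relative slack).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force BH step-up: q_i = min over j with p_(j) >= p_(i) of m p_(j)/j.
oracle_bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  q
}

# Two-sided conditional binomial test (small-p method): the Poisson limit of
# the exact NB split test for balanced group sizes.
oracle_binom_two_sided <- function(sA, s, prob = 0.5) {
  probs <- stats::dbinom(0:s, s, prob)
  p_obs <- probs[sA + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

make_reads <- function(seqs, prefix = "r") {
  tibble::tibble(read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
                 sequence = seqs, quality = strrep("I", nchar(seqs)))
}

# Small shared reference fixture built once per test run.
fixture_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- simulate_trna_reference(40, 10, seed = 101)
      cl <- cluster_trnas(ref$genes)
      cache <<- list(ref = ref, clusters = cl,
                     decoys = simulate_contigs(3, 800, "decoy", 102),
                     rrna = simulate_contigs(2, 1200, "rRNA", 103))
    }
    cache
  }
})
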