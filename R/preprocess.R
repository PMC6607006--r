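#' Trim the 3' sequencing adapter from reads
#'
#' Removes the adapter using 3'-ligated small-RNA semantics: the leftmost
#' exact occurrence of the full adapter is removed together with everything
#' downstream; otherwise the longest adapter *prefix* of at least
#' `min_overlap` nt that is a suffix of the read is removed (partial adapter
#' at the read end). Reads shorter than `min_len` after trimming are
#' discarded; reads without an adapter match pass through unchanged.
#' Matching is exact (no error tolerance) and N never matches.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`).
#' @param adapter Adapter sequence (default the TruSeq small-RNA 3' adapter).
#' @param min_overlap Minimum adapter-prefix overlap at the read 3' end.
#' @param min_len Minimum retained read length after trimming.
#' @return The trimmed read tibble, with attribute `trim_stats` (reads in,
#'   trimmed, discarded as too short).
#' @export
trim_adapter <- function(reads, adapter = TSRNA_ADAPTER, min_overlap = 5L,
                         min_len = 6L) {
  if (nchar(adapter) == 0L) stopf("adapter must be non-empty")
  n <- nrow(reads)
  if (n == 0L) {
    attr(reads, "trim_stats") <- tibble::tibble(
      reads_in = 0L, reads_trimmed = 0L, discarded_short = 0L, reads_out = 0L)
    return(reads)
  }
  keep_len <- nchar(reads$sequence)
  trimmed <- rep(FALSE, n)

  hit <- regexpr(adapter, reads$sequence, fixed = TRUE)
  full <- hit > 0L
  keep_len[full] <- hit[full] - 1L
  trimmed[full] <- TRUE

  max_k <- min(nchar(adapter) - 1L, max(keep_len))
  if (max_k >= min_overlap) {
    for (k in seq(from = max_k, to = min_overlap, by = -1L)) {
      pref <- substr(adapter, 1L, k)
      cand <- !trimmed & keep_len >= k &
        substr(reads$sequence, keep_len - k + 1L, keep_len) == pref
      keep_len[cand] <- keep_len[cand] - k
      trimmed[cand] <- TRUE
    }
  }

  out <- reads
  out$sequence <- substr(out$sequence, 1L, keep_len)
  out$quality <- substr(out$quality, 1L, keep_len)
  short <- nchar(out$sequence) < min_len
  out <- out[!short, , drop = FALSE]
  attr(out, "trim_stats") <- tibble::tibble(
    reads_in = n, reads_trimmed = sum(trimmed), discarded_short = sum(short),
    reads_out = nrow(out))
  out
}

#' Drop reads matching an rRNA reference
#'
#' A read is removed iff it has an ungapped (Hamming) placement with at most
#' `max_mismatches` mismatches on either strand of any rRNA sequence. Read
#' order is preserved.
#'
#' @param reads Read tibble.
#' @param rrna_reference Contig tibble (`contig_id`, `sequence`).
#' @param max_mismatches Mismatch tolerance (default 2, the constant used
#'   for every alignment in this pipeline).
#' @return The surviving reads, with attribute `rrna_stats`.
#' @export
filter_rrna <- function(reads, rrna_reference, max_mismatches = 2L) {
  if (is.null(rrna_reference) || nrow(rrna_reference) == 0L) {
    warning("empty rRNA reference; no reads filtered")
    attr(reads, "rrna_stats") <- tibble::tibble(
      reads_in = nrow(reads), rrna_dropped = 0L, reads_out = nrow(reads))
    return(reads)
  }
  if (nrow(reads) == 0L) {
    attr(reads, "rrna_stats") <- tibble::tibble(
      reads_in = 0L, rrna_dropped = 0L, reads_out = 0L)
    return(reads)
  }
  hits <- cpp_hamming_scan(reads$sequence, rrna_reference$sequence,
                           as.integer(max_mismatches),
                           rep(TRUE, nrow(rrna_reference)),
                           first_hit_only = TRUE)
  drop <- seq_len(nrow(reads)) %in% hits$read_idx
  out <- reads[!drop, , drop = FALSE]
  attr(out, "rrna_stats") <- tibble::tibble(
    reads_in = nrow(reads), rrna_dropped = sum(drop), reads_out = nrow(out))
  out
}

#' Keep reads within a length window
#'
#' @param reads Read tibble.
#' @param lo,hi Inclusive length bounds (default 18-35 nt, the analysis
#'   window for small-RNA species).
#' @return The surviving reads, with attribute `length_stats`.
#' @export
select_length <- function(reads, lo = 18L, hi = 35L) {
  if (lo > hi) stopf("lo must be <= hi")
  len <- nchar(reads$sequence)
  out <- reads[len >= lo & len <= hi, , drop = FALSE]
  attr(out, "length_stats") <- tibble::tibble(
    reads_in = nrow(reads), length_dropped = nrow(reads) - nrow(out),
    reads_out = nrow(out))
  out
}

#' Run the full read-cleanup pipeline
#'
#' Adapter trimming, rRNA removal and length selection, in that fixed order.
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_rrna
#' @inheritParams select_length
#' @return List with `reads` (cleaned tibble) and `report` (per-stage read
#'   accounting tibble).
#' @export
preprocess_reads <- function(reads, rrna_reference = NULL,
                             adapter = TSRNA_ADAPTER, min_overlap = 5L,
                             min_len = 6L, max_mismatches = 2L,
                             lo = 18L, hi = 35L) {
  t1 <- trim_adapter(reads, adapter, min_overlap, min_len)
  t2 <- filter_rrna(t1, rrna_reference, max_mismatches)
  t3 <- select_length(t2, lo, hi)
  report <- dplyr::bind_rows(
    tibble::tibble(stage = "trim_adapter",
                   reads_in = attr(t1, "trim_stats")$reads_in,
                   reads_dropped = attr(t1, "trim_stats")$discarded_short,
                   reads_out = attr(t1, "trim_stats")$reads_out),
    tibble::tibble(stage = "filter_rrna",
                   reads_in = attr(t2, "rrna_stats")$reads_in,
                   reads_dropped = attr(t2, "rrna_stats")$rrna_dropped,
                   reads_out = attr(t2, "rrna_stats")$reads_out),
    tibble::tibble(stage = "select_length",
                   reads_in = attr(t3, "length_stats")$reads_in,
                   reads_dropped = attr(t3, "length_stats")$length_dropped,
                   reads_out = attr(t3, "length_stats")$reads_out))
  list(reads = t3, report = report)
}
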