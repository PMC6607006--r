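#' Assemble alignment targets from clusters and contigs
#'
#' tRNA cluster representatives are searched on the forward strand only
#' (reads derive from the mature tRNA sense strand); decoy/genomic contigs
#' are searched on both strands.
#'
#' @param clusters Cluster tibble from [cluster_trnas()] (or NULL).
#' @param contigs Contig tibble (`contig_id`, `sequence`) (or NULL).
#' @return Tibble with `target_id`, `sequence`, `both_strands`, `is_trna`.
#' @export
align_targets <- function(clusters = NULL, contigs = NULL) {
  parts <- list()
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    parts$trna <- tibble::tibble(target_id = clusters$cluster_id,
                                 sequence = clusters$representative_sequence,
                                 both_strands = FALSE, is_trna = TRUE)
  }
  if (!is.null(contigs) && nrow(contigs) > 0L) {
    parts$contig <- tibble::tibble(target_id = contigs$contig_id,
                                   sequence = contigs$sequence,
                                   both_strands = TRUE, is_trna = FALSE)
  }
  if (length(parts) == 0L) stopf("no alignment targets supplied")
  dplyr::bind_rows(parts)
}

#' Align reads to reference targets (best-stratum Hamming)
#'
#' Ungapped alignment reporting *all* placements at each read's minimal
#' mismatch count (best stratum) within the `max_mismatches` bound.
#' Multi-mapping reads receive fractional weights `1/n` over their reported
#' placements so totals are conserved. No indels are considered, matching a
#' bowtie `-v`-style mismatch-only contract.
#'
#' @param reads Read tibble.
#' @param targets Target tibble from [align_targets()].
#' @param max_mismatches Maximum mismatches per placement (default 2).
#' @return Alignment tibble: `read_id`, `target_id`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), `strand`, `mismatches`,
#'   `weight`, `is_trna`.
#' @export
align_reads <- function(reads, targets, max_mismatches = 2L) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(read_id = character(), target_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer(),
                          weight = double(), is_trna = logical()))
  }
  hits <- cpp_hamming_scan(reads$sequence, targets$sequence,
                           as.integer(max_mismatches), targets$both_strands,
                           first_hit_only = FALSE)
  if (nrow(hits) == 0L) {
    return(align_reads(reads[0, ], targets, max_mismatches))
  }
  hits %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$read_idx) %>%
    dplyr::filter(.data$mismatches == min(.data$mismatches)) %>%
    dplyr::mutate(weight = 1 / dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      read_id = reads$read_id[.data$read_idx],
      target_id = targets$target_id[.data$target_idx],
      is_trna = targets$is_trna[.data$target_idx],
      end = .data$start + nchar(reads$sequence[.data$read_idx])) %>%
    dplyr::select("read_id", "target_id", "start", "end", "strand",
                  "mismatches", "weight", "is_trna")
}

#' Classify tRNA-aligned reads as tsRNAs
#'
#' A read is called a tsRNA iff it is 30-35 nt long and has at least one
#' tRNA-cluster alignment. Species is `5prime` when the alignment starts
#' within the first 4 nt of the cluster, `3prime` when it ends within the
#' last 4 nt of the cluster representative, and `internal` otherwise.
#' Reported coordinates are 1-based inclusive.
#'
#' @param alignments Alignment tibble restricted to tRNA cluster targets.
#' @param clusters Cluster tibble from [cluster_trnas()].
#' @return Call tibble: `read_id`, `cluster_id`, `start_1based`,
#'   `end_1based`, `length`, `species`, `is_tsrna`, `weight`.
#' @export
call_tsrnas <- function(alignments, clusters) {
  unknown <- setdiff(unique(alignments$target_id), clusters$cluster_id)
  if (length(unknown) > 0L) {
    stopf("alignment to unknown cluster_id '%s'", unknown[1])
  }
  rep_len <- stats::setNames(nchar(clusters$representative_sequence),
                             clusters$cluster_id)
  alignments %>%
    dplyr::mutate(
      cluster_id = .data$target_id,
      start_1based = .data$start + 1L,
      end_1based = .data$end,
      length = .data$end - .data$start,
      is_tsrna = .data$length >= 30L & .data$length <= 35L,
      species = dplyr::case_when(
        .data$start_1based <= 4L ~ "5prime",
        .data$end_1based >= rep_len[.data$cluster_id] - 3L ~ "3prime",
        TRUE ~ "internal")) %>%
    dplyr::select("read_id", "cluster_id", "start_1based", "end_1based",
                  "length", "species", "is_tsrna", "weight")
}

#' Per-base coverage fractions across tRNA clusters
#'
#' For every cluster position b, coverage is the weighted number of reads
#' whose alignment spans b divided by the total weighted number of
#' tRNA-mapped reads in the sample. The denominator is shared across all
#' clusters, so profiles are comparable within a sample and sum (times the
#' denominator) to the total weighted aligned read-bases.
#'
#' @param calls Call tibble from [call_tsrnas()] (one sample; typically
#'   pre-filtered to the read population of interest, e.g. 30-35 nt calls).
#' @param clusters Cluster tibble.
#' @return A `tsrna_coverage` tibble: `cluster_id`, `position` (1-based),
#'   `coverage`; attribute `denominator` holds the shared weighted read
#'   total.
#' @export
per_base_coverage <- function(calls, clusters) {
  denom <- sum(calls$weight)
  lens <- nchar(clusters$representative_sequence)
  if (denom == 0) {
    warning("no tRNA-mapped reads; coverage profiles are all zero")
  }
  profiles <- purrr::map2_dfr(clusters$cluster_id, lens, function(cid, L) {
    cov <- numeric(L)
    cc <- calls[calls$cluster_id == cid, , drop = FALSE]
    if (nrow(cc) > 0L) {
      # difference-array accumulation of interval weights
      d <- numeric(L + 1L)
      s <- pmax(cc$start_1based, 1L)
      e <- pmin(cc$end_1based, L)
      ok <- s <= e
      for (i in which(ok)) {
        d[s[i]] <- d[s[i]] + cc$weight[i]
        d[e[i] + 1L] <- d[e[i] + 1L] - cc$weight[i]
      }
      cov <- cumsum(d[seq_len(L)])
    }
    tibble::tibble(cluster_id = cid, position = seq_len(L),
                   coverage = if (denom > 0) cov / denom else cov)
  })
  attr(profiles, "denominator") <- denom
  class(profiles) <- c("tsrna_coverage", class(profiles))
  profiles
}

#' Fraction of genome-mapped reads that are tRNA-derived, by read length
#'
#' For each read length s in `lengths`, the number of distinct reads of
#' length s with at least one tRNA alignment divided by the number of
#' distinct reads of length s with at least one genomic alignment. Reads
#' with only tRNA alignments count as genome-mapped too (tRNA loci are
#' genomic). `NA` where the denominator is zero.
#'
#' @param genome_alignments Alignment tibble against genomic targets.
#' @param trna_alignments Alignment tibble against tRNA clusters.
#' @param lengths Integer vector of read lengths to report.
#' @return Tibble: `length`, `n_genome`, `n_trna`, `fraction`.
#' @export
trna_fraction_by_length <- function(genome_alignments, trna_alignments,
                                    lengths = 18:35) {
  len_of <- function(aln) {
    aln %>%
      dplyr::distinct(.data$read_id, .keep_all = TRUE) %>%
      dplyr::transmute(read_id = .data$read_id,
                       length = .data$end - .data$start)
  }
  trna <- len_of(trna_alignments)
  genome <- dplyr::bind_rows(len_of(genome_alignments), trna) %>%
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  purrr::map_dfr(lengths, function(s) {
    ng <- sum(genome$length == s)
    nt <- sum(trna$length == s)
    tibble::tibble(length = s, n_genome = ng, n_trna = nt,
                   fraction = if (ng > 0) nt / ng else NA_real_)
  })
}

#' Weighted tsRNA counts per cluster or anticodon
#'
#' Sums alignment weights of (by default 5') tsRNA calls per feature and
#' rounds half-up to integers for count-model input; the unrounded weighted
#' sum is retained for reports.
#'
#' @param calls Call tibble from [call_tsrnas()] (one sample).
#' @param clusters Cluster tibble (needed for anticodon grouping).
#' @param group_by `"cluster"` or `"anticodon"`.
#' @param species_filter Species to keep (default `"5prime"`); NULL keeps
#'   all tsRNA calls.
#' @return Tibble: `feature_id`, `count` (integer), `weighted_count`.
#' @export
count_tsrnas <- function(calls, clusters, group_by = c("cluster", "anticodon"),
                         species_filter = "5prime") {
  group_by <- match.arg(group_by)
  x <- calls %>% dplyr::filter(.data$is_tsrna)
  if (!is.null(species_filter)) {
    x <- x %>% dplyr::filter(.data$species %in% species_filter)
  }
  if (group_by == "anticodon") {
    key <- stats::setNames(paste0(clusters$amino_acid, clusters$anticodon),
                           clusters$cluster_id)
    x <- x %>% dplyr::mutate(feature_id = unname(key[.data$cluster_id]))
    if (anyNA(x$feature_id)) stopf("call references cluster with no anticodon")
  } else {
    x <- x %>% dplyr::mutate(feature_id = .data$cluster_id)
  }
  x %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::summarise(weighted_count = sum(.data$weight), .groups = "drop") %>%
    dplyr::mutate(count = as.integer(round_half_up(.data$weighted_count))) %>%
    dplyr::select("feature_id", "count", "weighted_count") %>%
    dplyr::arrange(.data$feature_id)
}

#' Export alignments as SAM
#'
#' Writes a minimal single-end SAM file (header built from the supplied
#' targets, NM tag carrying the mismatch count) so placements can be
#' inspected with standard tooling.
#'
#' @param alignments Alignment tibble from [align_reads()].
#' @param targets Target tibble used for the alignment.
#' @param reads Read tibble (for sequences/qualities).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, targets, reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", targets$target_id,
                     nchar(targets$sequence)), con)
  if (nrow(alignments) > 0L) {
    seqs <- stats::setNames(reads$sequence, reads$read_id)
    quals <- stats::setNames(reads$quality, reads$read_id)
    s <- seqs[alignments$read_id]
    q <- quals[alignments$read_id]
    neg <- alignments$strand == "-"
    s[neg] <- revcomp(s[neg])
    q[neg] <- vapply(strsplit(q[neg], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
    flag <- ifelse(neg, 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       alignments$read_id, flag, alignments$target_id,
                       alignments$start + 1L,
                       alignments$end - alignments$start, s, q,
                       alignments$mismatches), con)
  }
  invisible(path)
}
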