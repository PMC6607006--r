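#' Read a tRNA reference (FASTA plus annotation)
#'
#' Parses a GtRNAdb-style mature tRNA FASTA together with a tab-separated
#' annotation table and returns one row per tRNA gene. Sequences are
#' uppercased and U is converted to T; the anticodon position is taken from
#' the annotation when present and otherwise located with
#' [locate_anticodon()].
#'
#' @param fasta_path Path to a FASTA file whose headers carry the gene id
#'   (first whitespace-delimited token).
#' @param annotation_path Path to a TSV with columns `gene_id`,
#'   `amino_acid`, `anticodon` and `anticodon_start` (1-based position of the
#'   anticodon's first base; may be `NA`).
#' @return A tibble with columns `gene_id`, `amino_acid`, `anticodon`,
#'   `anticodon_start` and `sequence`.
#' @export
read_trna_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stopf("duplicate gene_id in FASTA: '%s'", ids[duplicated(ids)][1])
  }
  body <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTU]", body)
  if (any(bad)) {
    stopf("non-ACGTU character in sequence of record '%s'", ids[which(bad)[1]])
  }
  body <- chartr("U", "T", body)

  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           amino_acid = readr::col_character(),
                           anticodon = readr::col_character(),
                           anticodon_start = readr::col_integer()))
  if (!setequal(ann$gene_id, ids) || nrow(ann) != length(ids)) {
    stopf("annotation gene_ids do not match FASTA records")
  }
  genes <- tibble::tibble(gene_id = ids, sequence = unname(body)) %>%
    dplyr::left_join(ann, by = "gene_id") %>%
    dplyr::select("gene_id", "amino_acid", "anticodon", "anticodon_start",
                  "sequence")
  genes$anticodon <- toupper(chartr("U", "T", genes$anticodon))

  missing_start <- is.na(genes$anticodon_start)
  if (any(missing_start)) {
    genes$anticodon_start[missing_start] <- mapply(
      locate_anticodon,
      genes$sequence[missing_start], genes$anticodon[missing_start])
  }
  found <- substr(genes$sequence, genes$anticodon_start,
                  genes$anticodon_start + 2L)
  if (any(found != genes$anticodon)) {
    i <- which(found != genes$anticodon)[1]
    stopf("annotated anticodon_start of '%s' does not match its anticodon",
          genes$gene_id[i])
  }
  genes
}

#' Locate the anticodon triplet within a tRNA sequence
#'
#' Returns the 1-based position of the anticodon triplet, preferring the
#' first occurrence whose start falls in the canonical window \[30, 40\]
#' (standard tRNA architecture places the anticodon around position 34-36);
#' if no occurrence starts there, the first occurrence anywhere is used.
#'
#' @param sequence A DNA string (uppercase ACGT).
#' @param anticodon The 3-nt anticodon triplet.
#' @param window Integer window of admissible start positions tried first.
#' @return 1-based integer position of the anticodon's first base.
#' @export
locate_anticodon <- function(sequence, anticodon, window = c(30L, 40L)) {
  n <- nchar(sequence)
  if (n < 3L) stopf("sequence shorter than the anticodon")
  starts <- seq_len(n - 2L)
  hit <- starts[substring(sequence, starts, starts + 2L) == anticodon]
  if (length(hit) == 0L) {
    stopf("anticodon '%s' not found in sequence", anticodon)
  }
  in_window <- hit[hit >= window[1] & hit <= window[2]]
  if (length(in_window) > 0L) in_window[1] else hit[1]
}

#' Cluster tRNA genes by identity of their 5' sequence
#'
#' Collapses tRNA genes sharing an identical first `prefix_len` nucleotides
#' (their whole sequence when shorter) into clusters. This is the
#' multi-mapping remedy for 5'-derived fragments: reads from the tRNA 5' half
#' cannot distinguish loci that are identical over that span, so such loci
#' are quantified as one unit. Each cluster's representative is its longest
#' member sequence (ties broken by lexicographically smallest `gene_id`), so
#' 3'-end classification remains possible downstream.
#'
#' @param genes A tibble as returned by [read_trna_reference()].
#' @param prefix_len Prefix length defining cluster identity (default 50).
#' @return A tibble with one row per cluster: `cluster_id`, `prefix_key`,
#'   `n_members`, `member_ids` (comma-joined, sorted), `amino_acid`,
#'   `anticodon`, `anticodon_start` and `representative_sequence` (the last
#'   four taken from the representative member).
#' @export
cluster_trnas <- function(genes, prefix_len = 50L) {
  if (nrow(genes) == 0L) stopf("no genes to cluster")
  if (prefix_len < 1L) stopf("prefix_len must be >= 1")
  keys <- substr(genes$sequence, 1L, prefix_len)

  tagged <- genes %>% dplyr::mutate(prefix_key = keys)
  members <- tagged %>%
    dplyr::group_by(.data$prefix_key) %>%
    dplyr::summarise(
      n_members = dplyr::n(),
      member_ids = paste(sort(.data$gene_id), collapse = ","),
      first_member = min(.data$gene_id),
      .groups = "drop")
  reps <- tagged %>%
    dplyr::group_by(.data$prefix_key) %>%
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)), .data$gene_id,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("prefix_key", "amino_acid", "anticodon", "anticodon_start",
                  representative_sequence = "sequence")
  clusters <- members %>%
    dplyr::left_join(reps, by = "prefix_key") %>%
    dplyr::arrange(.data$first_member)

  clusters %>%
    dplyr::mutate(cluster_id = sprintf("cluster_%04d", dplyr::row_number())) %>%
    dplyr::select("cluster_id", "prefix_key", "n_members", "member_ids",
                  "amino_acid", "anticodon", "anticodon_start",
                  "representative_sequence")
}

#' Write tRNA clusters as TSV
#'
#' @param clusters Tibble from [cluster_trnas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_clusters <- function(clusters, path) {
  readr::write_tsv(
    clusters %>%
      dplyr::select("cluster_id", "prefix_key", "n_members", "member_ids",
                    "anticodon_start"),
    path)
  invisible(path)
}

#' Write gene sequences as FASTA
#'
#' @param genes Tibble with `gene_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_trna_fasta <- function(genes, path, width = 60L) {
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
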