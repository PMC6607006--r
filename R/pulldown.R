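#' Expression filter on normalized pulldown counts
#'
#' Keeps transcripts whose normalized count is strictly greater than
#' `min_value` in at least one sample (the classic "normalized value > 200
#' in at least one of the four samples" gate).
#'
#' @param norm Normalized count tibble (must carry the `normalized` flag set
#'   by [normalize_counts()]).
#' @param min_value Strict lower bound (default 200).
#' @return The surviving rows of `norm` (flag preserved).
#' @export
filter_expressed <- function(norm, min_value = 200) {
  if (!isTRUE(attr(norm, "normalized"))) {
    stopf("filter_expressed expects a normalized count matrix")
  }
  m <- count_matrix_values(norm)
  out <- norm[apply(m, 1, max) > min_value, , drop = FALSE]
  attr(out, "normalized") <- TRUE
  out
}

#' Two-sided Fisher exact p-value for one 2x2 table
#'
#' Thin, validated wrapper around `stats::fisher.test` (two-sided: sums all
#' tables with point probability at most the observed one, within 1e-7
#' relative slack). Exposed so every enrichment test in the package shares
#' one exact-test implementation.
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = (feature, rest),
#'   columns = (pulldown, control).
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stopf("negative cell count in 2x2 table")
  stats::fisher.test(matrix(round(cells), nrow = 2, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

#' Per-transcript Fisher association test for one condition
#'
#' For each transcript, builds the 2x2 table (transcript count vs rest of
#' library) x (tsRNA pulldown vs scramble control) from rounded normalized
#' counts and returns the two-sided Fisher exact p-value.
#'
#' @param norm Normalized count tibble containing the two sample columns.
#' @param ts_sample,scr_sample Names of the pulldown and control columns.
#' @return Tibble: `transcript_id`, `p`.
#' @export
fisher_association <- function(norm, ts_sample, scr_sample) {
  ts <- round_half_up(norm[[ts_sample]])
  scr <- round_half_up(norm[[scr_sample]])
  tot_ts <- sum(ts)
  tot_scr <- sum(scr)
  p <- vapply(seq_along(ts), function(i) {
    fisher_exact_p(ts[i], tot_ts - ts[i], scr[i], tot_scr - scr[i])
  }, double(1))
  tibble::tibble(transcript_id = norm$feature_id, p = p)
}

#' Full pulldown enrichment analysis
#'
#' Runs the complete transcript-association workflow on a raw 4-sample
#' pulldown count matrix (LIF_scr, LIF_ts, RA_scr, RA_ts): median-of-ratios
#' normalization, expression filter, per-condition tsRNA/scramble fold
#' changes (0.5 pseudo-count on zeros), per-condition two-sided Fisher
#' tests, Bonferroni correction (m = transcripts surviving the expression
#' filter), significance calling, cell-state allocation and, optionally,
#' target classification against a reference fold-change table.
#'
#' @param counts Raw count tibble with `feature_id` (or `transcript_id`)
#'   plus columns `LIF_scr`, `LIF_ts`, `RA_scr`, `RA_ts`.
#' @param reference_fc_table Optional tibble `transcript_id`,
#'   `reference_fc` for [classify_targets()].
#' @param min_value Expression-filter threshold.
#' @param fold Fold-change gate for significance.
#' @param alpha Adjusted-p significance level.
#' @param state_cutoff Fold cutoff for RA/LIF state allocation.
#' @return An `EnrichmentRecord` tibble (see [call_enriched()],
#'   [allocate_state()], [classify_targets()]).
#' @export
pulldown_analysis <- function(counts, reference_fc_table = NULL,
                              min_value = 200, fold = 2, alpha = 0.05,
                              state_cutoff = 2) {
  if ("transcript_id" %in% names(counts) && !"feature_id" %in% names(counts)) {
    counts <- dplyr::rename(counts, feature_id = "transcript_id")
  }
  need <- c("LIF_scr", "LIF_ts", "RA_scr", "RA_ts")
  if (!all(need %in% names(counts))) {
    stopf("counts must have columns %s", paste(need, collapse = ", "))
  }
  norm <- normalize_counts(counts)
  expressed <- filter_expressed(norm, min_value)

  fc_lif <- with_pseudo_ratio(expressed$LIF_ts, expressed$LIF_scr)
  fc_ra <- with_pseudo_ratio(expressed$RA_ts, expressed$RA_scr)

  p_lif <- fisher_association(expressed, "LIF_ts", "LIF_scr")$p
  p_ra <- fisher_association(expressed, "RA_ts", "RA_scr")$p

  records <- tibble::tibble(
    transcript_id = expressed$feature_id,
    LIF_scr = expressed$LIF_scr, LIF_ts = expressed$LIF_ts,
    RA_scr = expressed$RA_scr, RA_ts = expressed$RA_ts,
    fc_LIF = fc_lif, fc_RA = fc_ra,
    fisher_LIF = p_lif, fisher_RA = p_ra)
  records <- call_enriched(records, alpha = alpha, fold = fold)
  records <- allocate_state(records, cutoff = state_cutoff)
  if (!is.null(reference_fc_table)) {
    records <- classify_targets(records, reference_fc_table)
  }
  records
}

# ratio with 0.5 pseudo-count applied to zero numerators/denominators only
with_pseudo_ratio <- function(num, den) {
  num2 <- ifelse(num == 0, 0.5, num)
  den2 <- ifelse(den == 0, 0.5, den)
  num2 / den2
}

#' Flag significantly associated transcripts
#'
#' Applies per-condition Bonferroni correction (m = number of tested
#' transcripts) and flags a transcript as significant when, in at least one
#' condition, its fold change exceeds `fold` and its adjusted p-value is
#' below `alpha`. The union across conditions is the associated set.
#'
#' @param records Tibble with `fc_LIF`, `fc_RA`, `fisher_LIF`, `fisher_RA`.
#' @param alpha Significance level on the adjusted p-value.
#' @param fold Fold-change gate.
#' @return `records` with `bonf_LIF`, `bonf_RA`, `significant` added.
#' @export
call_enriched <- function(records, alpha = 0.05, fold = 2) {
  m <- nrow(records)
  records %>%
    dplyr::mutate(
      bonf_LIF = pmin(1, m * .data$fisher_LIF),
      bonf_RA = pmin(1, m * .data$fisher_RA),
      significant = (.data$fc_LIF > fold & .data$bonf_LIF < alpha) |
        (.data$fc_RA > fold & .data$bonf_RA < alpha))
}

#' Allocate significant transcripts to cell states
#'
#' The RA/LIF pulldown ratio r (normalized ts counts, 0.5 pseudo-count on
#' zeros) allocates each significant transcript: `RA_enriched` when
#' r > cutoff, `LIF_enriched` when r < 1/cutoff, `ubiquitous` when the
#' tsRNA/scramble fold change exceeds the gate in *both* conditions and r
#' lies within the band, `none` otherwise. Non-significant records get
#' state `none`.
#'
#' @param records Tibble from [call_enriched()].
#' @param cutoff Allocation fold cutoff (default 2).
#' @param fold Fold-change gate used for the ubiquitous class.
#' @return `records` with a `state` column.
#' @export
allocate_state <- function(records, cutoff = 2, fold = 2) {
  r <- with_pseudo_ratio(records$RA_ts, records$LIF_ts)
  records %>%
    dplyr::mutate(state = dplyr::case_when(
      !.data$significant ~ "none",
      r > cutoff ~ "RA_enriched",
      r < 1 / cutoff ~ "LIF_enriched",
      .data$fc_LIF > fold & .data$fc_RA > fold ~ "ubiquitous",
      TRUE ~ "none"))
}

#' Classify transcripts against a reference RA-response table
#'
#' `differentiation_responsive` when the reference RA-vs-stem fold change
#' exceeds 2, `pluripotency_associated` when below 0.5, `other` when in the
#' table but between, `unknown` when absent.
#'
#' @param records Tibble with `transcript_id`.
#' @param reference_fc_table Tibble `transcript_id`, `reference_fc`.
#' @return `records` with a `target_class` column.
#' @export
classify_targets <- function(records, reference_fc_table) {
  if (!all(c("transcript_id", "reference_fc") %in%
           names(reference_fc_table))) {
    stopf("reference_fc_table needs transcript_id and reference_fc columns")
  }
  fc <- reference_fc_table$reference_fc[
    match(records$transcript_id, reference_fc_table$transcript_id)]
  records %>%
    dplyr::mutate(target_class = dplyr::case_when(
      is.na(fc) ~ "unknown",
      fc > 2 ~ "differentiation_responsive",
      fc < 0.5 ~ "pluripotency_associated",
      TRUE ~ "other"))
}

#' Summarise a pulldown enrichment result
#'
#' @param records Tibble from [pulldown_analysis()].
#' @return One-row tibble with tested/associated counts and the per-state
#'   partition of the associated set.
#' @export
pulldown_summary <- function(records) {
  tibble::tibble(
    n_tested = nrow(records),
    n_associated = sum(records$significant),
    n_RA_enriched = sum(records$state == "RA_enriched"),
    n_LIF_enriched = sum(records$state == "LIF_enriched"),
    n_ubiquitous = sum(records$state == "ubiquitous"))
}
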