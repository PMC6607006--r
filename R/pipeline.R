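#' Build a pipeline run configuration
#'
#' Collects every stage parameter, with the package defaults, into one
#' serializable list. All randomness in a run flows from the single
#' top-level `seed` (per-stage seeds are derived from it), so a completed
#' run is exactly reproducible from its echoed configuration.
#'
#' @param seed Top-level integer seed.
#' @param n_genes,n_anticodons tRNA reference simulation size.
#' @param n_reads Reads per simulated library.
#' @param n_replicates Libraries per condition (conditions: LIF, RA).
#' @param tsrna_fraction_LIF,tsrna_fraction_RA Per-condition tsRNA class
#'   fractions (RA higher, as differentiation increases the tsRNA pool).
#' @param error_rate Per-base sequencing error rate.
#' @param adapter 3' adapter sequence.
#' @param max_mismatches Alignment mismatch bound.
#' @param prefix_len Cluster prefix length.
#' @param min_norm Pulldown expression filter threshold.
#' @param fold Fold-change gate (pulldown and emPAI).
#' @param alpha Significance level.
#' @param n_transcripts,n_enriched Pulldown simulation size.
#' @param n_proteins,n_empai_enriched emPAI simulation size.
#' @param kd_nM,binding_cv Binding-series simulation parameters.
#' @param simulate_reference Simulate the tRNA reference (`TRUE`) or read it
#'   from `reference_fasta`/`reference_annotation`.
#' @param reference_fasta,reference_annotation Paths used when
#'   `simulate_reference` is `FALSE`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_genes = 60L, n_anticodons = 12L,
                            n_reads = 3000L, n_replicates = 2L,
                            tsrna_fraction_LIF = 0.35,
                            tsrna_fraction_RA = 0.55,
                            error_rate = 0.001, adapter = TSRNA_ADAPTER,
                            max_mismatches = 2L, prefix_len = 50L,
                            min_norm = 200, fold = 2, alpha = 0.05,
                            n_transcripts = 2000L, n_enriched = 60L,
                            n_proteins = 300L, n_empai_enriched = 16L,
                            kd_nM = 33, binding_cv = 0.02,
                            simulate_reference = TRUE,
                            reference_fasta = NULL,
                            reference_annotation = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage %s: %s", stage, conditionMessage(e))
  })
}

log_line <- function(stage, level, msg) {
  message(sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg))
}

# Every output table opens with a comment naming the tool version and the
# configuration hash, so artifacts are traceable to their run.
write_output_tsv <- function(df, path, config_hash) {
  header <- sprintf("# tsrnakit %s config=%s",
                    as.character(utils::packageVersion("tsrnakit")),
                    config_hash)
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> align/call -> quantify ->
#' differential -> pulldown -> interactome on synthetic data (or a supplied
#' tRNA reference), writing every stage artifact as TSV (plus FASTA/FASTQ
#' inputs and the resolved configuration as YAML) under `outdir`. The run
#' is deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the main result objects.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(outdir) || is.null(outdir)) stopf("outdir must be given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  seed <- config$seed

  # --- reference -----------------------------------------------------------
  ref <- with_stage("reference", {
    if (isTRUE(config$simulate_reference)) {
      sim <- simulate_trna_reference(config$n_genes, config$n_anticodons,
                                     seed = derive_seed(seed, 1L))
      write_trna_reference(sim, file.path(outdir, "trna_reference.fasta"),
                           file.path(outdir, "trna_annotation.tsv"))
      sim$genes
    } else {
      if (is.null(config$reference_fasta)) {
        stopf("config field 'reference_fasta' is required when simulate_reference is FALSE")
      }
      if (is.null(config$reference_annotation)) {
        stopf("config field 'reference_annotation' is required when simulate_reference is FALSE")
      }
      read_trna_reference(config$reference_fasta, config$reference_annotation)
    }
  })
  clusters <- with_stage("cluster", cluster_trnas(ref, config$prefix_len))
  write_output_tsv(clusters %>% dplyr::select(-"representative_sequence"),
                   file.path(outdir, "clusters.tsv"), cfg_hash)
  log_line("cluster", "INFO",
           sprintf("%d genes -> %d clusters", nrow(ref), nrow(clusters)))

  decoys <- simulate_contigs(3L, 1200L, "decoy", derive_seed(seed, 2L))
  rrna <- simulate_contigs(2L, 1500L, "rRNA", derive_seed(seed, 3L))
  targets <- align_targets(clusters, decoys)

  # --- libraries: preprocess, align, call, quantify ------------------------
  conditions <- c(LIF = config$tsrna_fraction_LIF,
                  RA = config$tsrna_fraction_RA)
  k <- min(5L, nrow(clusters))
  base_w <- seq_len(k) / sum(seq_len(k))
  cluster_w <- list(
    LIF = stats::setNames(base_w, clusters$cluster_id[seq_len(k)]),
    RA = stats::setNames(rev(base_w), clusters$cluster_id[seq_len(k)]))

  sample_results <- list()
  reports <- list()
  counts_by_sample <- list()
  for (cond in names(conditions)) {
    for (rep_i in seq_len(config$n_replicates)) {
      sample_id <- sprintf("%s_rep%d", cond, rep_i)
      lib <- with_stage("simulate", simulate_small_rna_library(
        library_config(
          n_reads = config$n_reads,
          tsrna_fraction = conditions[[cond]],
          mirna_fraction = 0.2, rrna_fraction = 0.1,
          producing_cluster_weights = cluster_w[[cond]],
          adapter = config$adapter, error_rate = config$error_rate,
          seed = derive_seed(seed, 10L + length(sample_results))),
        clusters, decoys, rrna))
      write_fastq(lib$reads, file.path(outdir, paste0(sample_id, ".fastq")))
      pp <- with_stage("preprocess", preprocess_reads(
        lib$reads, rrna, adapter = config$adapter,
        max_mismatches = config$max_mismatches))
      aln <- with_stage("align", align_reads(pp$reads, targets,
                                             config$max_mismatches))
      calls <- with_stage("call", call_tsrnas(
        aln %>% dplyr::filter(.data$is_trna), clusters))
      cts <- with_stage("quantify", count_tsrnas(calls, clusters))
      sample_results[[sample_id]] <- list(lib = lib, reads = pp$reads,
                                          alignments = aln, calls = calls)
      reports[[sample_id]] <- pp$report %>%
        dplyr::mutate(sample = sample_id, .before = 1)
      counts_by_sample[[sample_id]] <- cts %>%
        dplyr::select("feature_id", !!sample_id := "count")
      log_line("call", "INFO", sprintf("%s: %d tsRNA calls", sample_id,
                                       sum(calls$is_tsrna)))
    }
  }
  write_output_tsv(dplyr::bind_rows(reports),
                   file.path(outdir, "preprocess_report.tsv"), cfg_hash)

  first <- sample_results[[1]]
  write_output_tsv(first$calls, file.path(outdir, "tsrna_calls.tsv"), cfg_hash)
  coverage <- per_base_coverage(
    first$calls %>% dplyr::filter(.data$is_tsrna), clusters)
  write_output_tsv(tibble::as_tibble(coverage),
                   file.path(outdir, "coverage.tsv"), cfg_hash)
  fraction <- trna_fraction_by_length(
    first$alignments %>% dplyr::filter(!.data$is_trna),
    first$alignments %>% dplyr::filter(.data$is_trna))
  write_output_tsv(fraction, file.path(outdir, "fraction_by_length.tsv"),
                   cfg_hash)

  # --- differential tsRNA abundance ---------------------------------------
  tsrna_counts <- purrr::reduce(counts_by_sample,
                                dplyr::full_join, by = "feature_id") %>%
    dplyr::mutate(dplyr::across(-"feature_id", ~tidyr::replace_na(.x, 0L))) %>%
    dplyr::arrange(.data$feature_id)
  write_output_tsv(tsrna_counts, file.path(outdir, "tsrna_counts.tsv"),
                   cfg_hash)
  groups <- stats::setNames(sub("_rep\\d+$", "", names(counts_by_sample)),
                            names(counts_by_sample))
  de <- with_stage("diffexp", {
    sf <- size_factors(tsrna_counts)
    write_output_tsv(sf, file.path(outdir, "size_factors.tsv"), cfg_hash)
    nb_test(tsrna_counts, groups, sf = sf)
  })
  write_output_tsv(tibble::as_tibble(de), file.path(outdir, "de_results.tsv"),
                   cfg_hash)

  # --- pulldown ------------------------------------------------------------
  pull <- with_stage("pulldown", {
    sim <- simulate_pulldown_counts(config$n_transcripts, config$n_enriched,
                                    seed = derive_seed(seed, 20L))
    fcref <- simulate_reference_fc_table(sim$counts$transcript_id,
                                         seed = derive_seed(seed, 21L))
    records <- pulldown_analysis(sim$counts, fcref$table,
                                 min_value = config$min_norm,
                                 fold = config$fold, alpha = config$alpha)
    list(records = records, manifest = sim$manifest)
  })
  write_output_tsv(pull$records, file.path(outdir, "pulldown_records.tsv"),
                   cfg_hash)
  write_output_tsv(pulldown_summary(pull$records),
                   file.path(outdir, "pulldown_summary.tsv"), cfg_hash)

  # --- interactome ---------------------------------------------------------
  inter <- with_stage("interactome", {
    sim <- simulate_empai_table(config$n_proteins, config$n_empai_enriched,
                                seed = derive_seed(seed, 30L))
    records <- sim$table %>% clean_empai() %>%
      empai_enriched(fold = config$fold)
    hits <- records$protein_id[records$enriched_RA]
    sets <- synthetic_gene_sets(records$protein_id, hits,
                                seed = derive_seed(seed, 31L))
    gs <- geneset_enrichment(hits, records$protein_id, sets)
    series <- simulate_binding_series(kd_nM = config$kd_nM,
                                      cv = config$binding_cv,
                                      seed = derive_seed(seed, 32L))
    fit <- fit_kd(series)
    list(records = records, genesets = gs, fit = fit)
  })
  write_output_tsv(inter$records, file.path(outdir, "empai_records.tsv"),
                   cfg_hash)
  write_output_tsv(inter$genesets,
                   file.path(outdir, "geneset_enrichment.tsv"), cfg_hash)
  write_output_tsv(glance(inter$fit), file.path(outdir, "kd_fit.tsv"),
                   cfg_hash)

  yaml::write_yaml(unclass(config), file.path(outdir, "run_config.yaml"))
  log_line("done", "INFO", sprintf("artifacts written to %s", outdir))
  invisible(list(clusters = clusters, samples = sample_results,
                 counts = tsrna_counts, de = de, pulldown = pull$records,
                 interactome = inter))
}

# Small synthetic gene-set collection over the detected proteins: one set
# enriched in the hits, the rest random background draws.
synthetic_gene_sets <- function(background, hits, n_sets = 5L, seed = 1L) {
  withr::with_seed(seed, {
    sets <- list()
    if (length(hits) >= 2L) {
      sets[["HIT_LIKE_SET"]] <- unique(c(
        hits, sample(background, min(10L, length(background)))))
    }
    for (i in seq_len(n_sets)) {
      sets[[sprintf("RANDOM_SET_%d", i)]] <-
        sample(background, min(30L, length(background)))
    }
    sets
  })
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
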