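test_that("aligner reports best-stratum placements with conserved weights", {
  fx <- fixture_reference()
  cl <- fx$clusters
  targets <- align_targets(cl, fx$decoys)

  r1 <- make_reads(substr(cl$representative_sequence[1], 1, 33))
  a1 <- align_reads(r1, targets)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$start, 0L)
  expect_equal(a1$mismatches, 0L)
  expect_equal(a1$weight, 1)

  # identical 33-nt prefix planted on two synthetic clusters
  two <- tibble::tibble(
    cluster_id = c("cA", "cB"), prefix_key = "", n_members = 1L,
    member_ids = c("a", "b"), amino_acid = "Gly", anticodon = "GCC",
    anticodon_start = 34L,
    representative_sequence = c(paste0(strrep("ACGTG", 8), strrep("A", 40)),
                                paste0(strrep("ACGTG", 8), strrep("C", 40))))
  a2 <- align_reads(make_reads(strrep("ACGTG", 8)), align_targets(two))
  expect_equal(nrow(a2), 2L)
  expect_equal(a2$weight, c(0.5, 0.5))
  expect_equal(sum(a2$weight), 1)
})

test_that("aligner agrees with an independent pure-R exhaustive scan", {
  fx <- fixture_reference()
  cl <- fx$clusters[1:4, ]
  decoy <- fx$decoys[1, ]
  targets <- align_targets(cl, decoy)
  cfg <- library_config(n_reads = 150, tsrna_fraction = 0.6,
                        mirna_fraction = 0.2, rrna_fraction = 0,
                        producing_cluster_weights =
                          stats::setNames(rep(0.25, 4), cl$cluster_id),
                        error_rate = 0.02, seed = 21)
  lib <- simulate_small_rna_library(cfg, cl, decoy, NULL)
  reads <- trim_adapter(lib$reads)

  got <- align_reads(reads, targets) %>%
    dplyr::mutate(read_idx = match(read_id, reads$read_id),
                  target_idx = match(target_id, targets$target_id)) %>%
    dplyr::arrange(read_idx, target_idx, start, strand)
  want <- oracle_best_stratum(
    oracle_hamming_scan(reads$sequence, targets$sequence, 2,
                        targets$both_strands))
  want <- want[order(want$read_idx, want$target_idx, want$start, want$strand), ]
  expect_equal(got$read_idx, want$read_idx)
  expect_equal(got$target_idx, want$target_idx)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$mismatches, want$mismatches)
  expect_equal(got$weight, want$weight)
})

test_that("tsRNA calls apply the 30-35 nt and 5' start rules", {
  fx <- fixture_reference()
  cl <- fx$clusters
  targets <- align_targets(cl)
  rep1 <- cl$representative_sequence[1]
  L1 <- nchar(rep1)
  reads <- make_reads(c(
    substr(rep1, 1, 33),            # 33 nt from nt 1 -> 5prime tsRNA
    substr(rep1, 1, 22),            # 22 nt -> not a tsRNA (length rule)
    substr(rep1, L1 - 31, L1),      # 32 nt ending at the 3' end -> 3prime
    substr(rep1, 10, 41)))          # 32 nt internal
  calls <- call_tsrnas(align_reads(reads, targets), cl)
  calls <- calls[match(reads$read_id, calls$read_id), ]
  expect_equal(calls$is_tsrna, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(calls$species, c("5prime", "5prime", "3prime", "internal"))
  expect_equal(calls$start_1based[1], 1L)
  expect_equal(calls$end_1based[1], 33L)

  bad <- dplyr::mutate(align_reads(reads, targets),
                       target_id = "no_such_cluster")
  expect_error(call_tsrnas(bad, cl), "unknown cluster_id")
})

test_that("tsRNA call set grows monotonically with allowed mismatches", {
  fx <- fixture_reference()
  targets <- align_targets(fx$clusters, fx$decoys)
  cfg <- library_config(n_reads = 600, tsrna_fraction = 0.7,
                        mirna_fraction = 0.1, rrna_fraction = 0,
                        error_rate = 0.03, seed = 31)
  lib <- simulate_small_rna_library(cfg, fx$clusters, fx$decoys, NULL)
  reads <- trim_adapter(lib$reads)
  called <- lapply(0:2, function(mm) {
    aln <- align_reads(reads, targets, max_mismatches = mm)
    calls <- call_tsrnas(dplyr::filter(aln, is_trna), fx$clusters)
    unique(calls$read_id[calls$is_tsrna])
  })
  expect_true(all(called[[1]] %in% called[[2]]))
  expect_true(all(called[[2]] %in% called[[3]]))
})

test_that("per-base coverage uses the shared denominator and conserves mass", {
  fx <- fixture_reference()
  cl <- fx$clusters
  targets <- align_targets(cl)

  one <- make_reads(substr(cl$representative_sequence[1], 1, 33))
  cov1 <- per_base_coverage(call_tsrnas(align_reads(one, targets), cl), cl)
  c1 <- cov1[cov1$cluster_id == cl$cluster_id[1], ]
  expect_equal(c1$coverage[1:33], rep(1, 33))
  expect_equal(sum(c1$coverage), 33)
  expect_equal(sum(cov1$coverage[cov1$cluster_id != cl$cluster_id[1]]), 0)

  two <- make_reads(c(substr(cl$representative_sequence[1], 1, 33),
                      substr(cl$representative_sequence[2], 1, 31)))
  cov2 <- per_base_coverage(call_tsrnas(align_reads(two, targets), cl), cl)
  expect_equal(max(cov2$coverage), 0.5)

  cfg <- library_config(n_reads = 800, tsrna_fraction = 1,
                        mirna_fraction = 0, rrna_fraction = 0,
                        error_rate = 0, seed = 41)
  lib <- simulate_small_rna_library(cfg, cl, fx$decoys, fx$rrna)
  calls <- call_tsrnas(align_reads(trim_adapter(lib$reads), targets), cl)
  calls <- dplyr::filter(calls, is_tsrna)
  cov <- per_base_coverage(calls, cl)
  denom <- attr(cov, "denominator")
  expect_equal(sum(cov$coverage) * denom, sum(calls$weight * calls$length))
  # direct recount from manifest intervals for one cluster
  cid <- cl$cluster_id[which.max(table(calls$cluster_id))]
  mf <- lib$manifest[lib$manifest$source_id == cid, ]
  pos <- 20
  direct <- sum(mf$start <= pos & mf$end >= pos)
  expect_equal(cov$coverage[cov$cluster_id == cid & cov$position == pos],
               direct / denom)

  expect_warning(per_base_coverage(calls[0, ], cl), "all zero|no tRNA")
})

test_that("tRNA fraction by read length handles full and empty strata", {
  fx <- fixture_reference()
  targets <- align_targets(fx$clusters, fx$decoys)
  reads <- make_reads(c(substr(fx$clusters$representative_sequence[1], 1, 31),
                        substr(fx$clusters$representative_sequence[2], 1, 31),
                        substr(fx$decoys$sequence[1], 1, 25)))
  aln <- align_reads(reads, targets)
  fr <- trna_fraction_by_length(dplyr::filter(aln, !is_trna),
                                dplyr::filter(aln, is_trna))
  expect_equal(fr$fraction[fr$length == 31], 1)
  expect_equal(fr$fraction[fr$length == 25], 0)
  expect_true(is.na(fr$fraction[fr$length == 20]))
})

test_that("tsRNA counting rounds weighted sums half-up", {
  calls <- tibble::tibble(
    read_id = sprintf("r%02d", 1:12),
    cluster_id = c(rep("cluster_0001", 10), "cluster_0002", "cluster_0002"),
    start_1based = 1L, end_1based = 33L, length = 33L,
    species = "5prime", is_tsrna = TRUE,
    weight = c(rep(1, 10), 0.5, 0.5))
  fx <- fixture_reference()
  ct <- count_tsrnas(calls, fx$clusters)
  expect_equal(ct$count[ct$feature_id == "cluster_0001"], 10L)
  expect_equal(ct$count[ct$feature_id == "cluster_0002"], 1L)
  expect_equal(ct$weighted_count[ct$feature_id == "cluster_0002"], 1)

  by_ac <- count_tsrnas(calls, fx$clusters, group_by = "anticodon")
  expect_equal(sum(by_ac$weighted_count), sum(ct$weighted_count))
})

test_that("SAM export round-trips coordinates through samtools-style fields", {
  fx <- fixture_reference()
  targets <- align_targets(fx$clusters[1:2, ], fx$decoys[1, ])
  reads <- make_reads(c(substr(fx$clusters$representative_sequence[1], 1, 33),
                        oracle_revcomp(substr(fx$decoys$sequence[1], 51, 80))))
  aln <- align_reads(reads, targets)
  sam <- file.path(withr::local_tempdir(), "out.sam")
  write_sam(aln, targets, reads, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), nrow(aln))
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f[4]), aln$start[1] + 1L)
  expect_equal(f[12], sprintf("NM:i:%d", aln$mismatches[1]))
  neg <- strsplit(body[aln$strand == "-"][1], "\t")[[1]]
  expect_equal(as.integer(neg[2]), 16L)
})
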