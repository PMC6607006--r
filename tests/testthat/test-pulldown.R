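test_that("expression filter is strict and requires the normalized flag", {
  counts <- tibble::tibble(feature_id = c("t1", "t2", "t3"),
                           LIF_scr = c(200, 201, 5), LIF_ts = c(120, 10, 10),
                           RA_scr = c(10, 10, 10), RA_ts = c(150, 10, 10))
  expect_error(filter_expressed(counts), "normalized")
  norm <- counts
  attr(norm, "normalized") <- TRUE
  kept <- filter_expressed(norm)
  expect_equal(kept$feature_id, "t2")  # 200.0 is dropped, strictly > 200
})

test_that("Fisher exact p matches closed forms and enumeration", {
  expect_equal(fisher_exact_p(10, 990, 10, 990), 1)
  expect_equal(fisher_exact_p(5, 0, 0, 5), 1 / 126, tolerance = 1e-10)
  expect_error(fisher_exact_p(-1, 2, 3, 4), "negative")

  withr::with_seed(8, {
    for (i in 1:50) {
      a <- sample(0:15, 1); b <- sample(0:15, 1)
      c <- sample(0:15, 1); d <- sample(0:15, 1)
      if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
      expect_equal(fisher_exact_p(a, b, c, d),
                   oracle_fisher_two_sided(a, b, c, d), tolerance = 1e-10)
      # invariance under simultaneous row + column swap
      expect_equal(fisher_exact_p(a, b, c, d), fisher_exact_p(d, c, b, a),
                   tolerance = 1e-12)
      # ts/scr label swap leaves p unchanged
      expect_equal(fisher_exact_p(a, b, c, d), fisher_exact_p(c, d, a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("significance calling gates on both fold change and Bonferroni", {
  records <- tibble::tibble(
    transcript_id = c("hit", "fc_gate", "p_gate"),
    LIF_ts = c(300, 300, 300), LIF_scr = c(100, 200, 100),
    RA_ts = c(10, 10, 10), RA_scr = c(10, 10, 10),
    fc_LIF = c(3, 1.5, 3), fc_RA = 1,
    fisher_LIF = c(1e-6, 1e-6, 0.03), fisher_RA = 1)
  out <- call_enriched(records, alpha = 0.05)
  expect_equal(out$bonf_LIF, pmin(1, 3 * records$fisher_LIF))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("state allocation follows the twofold RA/LIF ratio rule", {
  records <- tibble::tibble(
    transcript_id = c("ra", "lif", "ubi", "band_no_fc", "ns"),
    LIF_ts = c(50, 400, 100, 100, 100), LIF_scr = c(20, 50, 30, 80, 30),
    RA_ts = c(400, 50, 100, 100, 100), RA_scr = c(50, 20, 30, 80, 30),
    fc_LIF = c(2.5, 8, 3.3, 1.2, 3.3), fc_RA = c(8, 2.5, 3.3, 1.2, 3.3),
    fisher_LIF = 1e-9, fisher_RA = 1e-9,
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- allocate_state(records)
  expect_equal(out$state, c("RA_enriched", "LIF_enriched", "ubiquitous",
                            "none", "none"))
})

test_that("target classification uses the reference fold-change table", {
  records <- tibble::tibble(transcript_id = c("up", "down", "mid", "missing"))
  ref <- tibble::tibble(transcript_id = c("up", "down", "mid"),
                        reference_fc = c(4, 0.25, 1.2))
  out <- classify_targets(records, ref)
  expect_equal(out$target_class,
               c("differentiation_responsive", "pluripotency_associated",
                 "other", "unknown"))
  expect_error(classify_targets(records, tibble::tibble(x = 1)),
               "reference_fc")

  ids <- sprintf("tx_%03d", 1:400)
  sim <- simulate_reference_fc_table(ids, seed = 3)
  got <- classify_targets(tibble::tibble(transcript_id = ids), sim$table)
  expect_equal(got$target_class, sim$manifest$class)
})

test_that("planted pulldown enrichment is recovered with few false calls", {
  sim <- simulate_pulldown_counts(2000, 50, true_fc = 4, baseline_mean = 200,
                                  dispersion = 0, seed = 19)
  fcref <- simulate_reference_fc_table(sim$counts$transcript_id, seed = 20)
  rec <- pulldown_analysis(sim$counts, fcref$table)
  called <- rec$transcript_id[rec$significant]
  expect_gte(mean(sim$manifest$transcript_id %in% called), 0.9)
  expect_lte(sum(!called %in% sim$manifest$transcript_id), 2)

  states <- rec$state[match(sim$manifest$transcript_id, rec$transcript_id)]
  ok <- !is.na(states)
  acc <- tapply(states[ok] == sim$manifest$state[ok], sim$manifest$state[ok],
                mean)
  expect_true(all(acc >= 0.9))
})

test_that("raising thresholds never adds transcripts to any output set", {
  sim <- simulate_pulldown_counts(1000, 40, true_fc = 4, baseline_mean = 200,
                                  dispersion = 0, seed = 23)
  loose <- pulldown_analysis(sim$counts, min_value = 100, fold = 2)
  tight <- pulldown_analysis(sim$counts, min_value = 300, fold = 2)
  expect_true(all(tight$transcript_id %in% loose$transcript_id))
  expect_true(all(tight$transcript_id[tight$significant] %in%
                  loose$transcript_id[loose$significant]))

  s2 <- allocate_state(call_enriched(loose), cutoff = 2)
  s4 <- allocate_state(call_enriched(loose), cutoff = 4)
  expect_true(all(s4$transcript_id[s4$state == "RA_enriched"] %in%
                  s2$transcript_id[s2$state == "RA_enriched"]))
})

test_that("ts/scr column swap inverts fold changes, preserves p-values", {
  sim <- simulate_pulldown_counts(300, 10, true_fc = 4, baseline_mean = 300,
                                  dispersion = 0, seed = 29)
  swapped <- sim$counts[, c("transcript_id", "LIF_ts", "LIF_scr",
                            "RA_ts", "RA_scr")]
  names(swapped) <- c("transcript_id", "LIF_scr", "LIF_ts",
                      "RA_scr", "RA_ts")
  r1 <- pulldown_analysis(sim$counts, min_value = 0)
  r2 <- pulldown_analysis(swapped, min_value = 0)
  expect_equal(r2$fc_LIF, 1 / r1$fc_LIF, tolerance = 1e-9)
  expect_equal(r2$fisher_LIF, r1$fisher_LIF, tolerance = 1e-9)
})

test_that("pulldown summary partitions the associated set", {
  sim <- simulate_pulldown_counts(800, 30, true_fc = 4, baseline_mean = 200,
                                  dispersion = 0, seed = 31)
  rec <- pulldown_analysis(sim$counts)
  s <- pulldown_summary(rec)
  expect_equal(s$n_associated,
               s$n_RA_enriched + s$n_LIF_enriched + s$n_ubiquitous +
                 sum(rec$significant & rec$state == "none"))
  p <- plot_pulldown_states(rec)
  expect_s3_class(p, "ggplot")
})
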