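test_that("emPAI cleaning replaces non-detects and flags bead dominance", {
  raw <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    beads = c(-1, 0.5, 0.01),
    LIF = c(0.30, 0.20, 0.50),
    RA = c(0.90, 0.30, 0.04))
  rec <- clean_empai(raw)
  expect_equal(rec$empai_beads[1], 0.01)  # -1 -> lowest detected value
  expect_equal(rec$adj_LIF, raw$LIF - c(0.01, 0.5, 0.01))
  expect_equal(rec$discarded_bead_dominant, c(FALSE, TRUE, FALSE))
  expect_error(clean_empai(dplyr::mutate(raw, RA = c(-0.2, 0.3, 0.4))),
               "non-sentinel")
})

test_that("emPAI cleaning is idempotent and scale-equivariant", {
  em <- simulate_empai_table(200, 12, seed = 5, cv = 0.2)
  r1 <- clean_empai(em$table)
  r2 <- clean_empai(dplyr::select(r1, "protein_id", beads = "empai_beads",
                                  LIF = "empai_LIF", RA = "empai_RA"))
  expect_equal(r2$empai_beads, r1$empai_beads)
  expect_equal(r2$adj_RA, r1$adj_RA)
  expect_equal(r2$discarded_bead_dominant, r1$discarded_bead_dominant)

  for (c_scale in c(0.01, 7)) {
    scaled <- em$table
    sentinel <- scaled$beads == -1
    scaled$beads[!sentinel] <- scaled$beads[!sentinel] * c_scale
    scaled$LIF <- scaled$LIF * c_scale
    scaled$RA <- scaled$RA * c_scale
    rs <- empai_enriched(clean_empai(scaled))
    r0 <- empai_enriched(r1)
    expect_equal(rs$enriched_RA, r0$enriched_RA)
    expect_equal(rs$enriched_LIF, r0$enriched_LIF)
    expect_equal(rs$discarded_bead_dominant, r0$discarded_bead_dominant)
    expect_equal(rs$log2_ratio, r0$log2_ratio, tolerance = 1e-9)
  }
})

test_that("twofold emPAI flagging recovers the planted set exactly at cv 0", {
  em <- simulate_empai_table(500, 20, seed = 3, cv = 0)
  rec <- empai_enriched(clean_empai(em$table))
  expect_setequal(rec$protein_id[rec$enriched_RA],
                  em$manifest$protein_id[em$manifest$enriched == "RA"])
  expect_setequal(rec$protein_id[rec$enriched_LIF],
                  em$manifest$protein_id[em$manifest$enriched == "LIF"])
  expect_equal(rec$protein_id[rec$discarded_bead_dominant],
               em$manifest$protein_id[em$manifest$bead_dominant])

  none <- simulate_empai_table(100, 0, seed = 4, cv = 0, n_bead_dominant = 0)
  r0 <- empai_enriched(clean_empai(none$table))
  expect_false(any(r0$enriched_RA | r0$enriched_LIF))

  # a protein with RA = 4x the bead-subtracted LIF value is flagged
  hand <- tibble::tibble(protein_id = c("q", "bgmin"),
                         beads = c(0.10, 0.01),
                         LIF = c(0.30, 0.30), RA = c(0.90, 0.30))
  rh <- empai_enriched(clean_empai(hand))
  expect_true(rh$enriched_RA[1])
})

test_that("gene-set enrichment shares the exact Fisher implementation", {
  bg <- sprintf("g%03d", 1:200)
  hits <- bg[1:20]
  sets <- list(HIT = bg[1:20], OTHER = bg[50:80], OUTSIDE = c("x1", "x2"))
  expect_warning(res <- geneset_enrichment(hits, bg, sets),
                 "without background overlap")
  expect_equal(nrow(res), 2L)
  expect_lt(res$p[res$set == "HIT"], res$p[res$set == "OTHER"])
  expect_equal(res$q, bh_adjust(res$p))

  # toy counts checked against direct hypergeometric enumeration
  expect_equal(fisher_exact_p(8, 2, 92, 898),
               oracle_fisher_two_sided(8, 2, 92, 898), tolerance = 1e-10)

  # null draws: uniform hits give roughly nominal small-p rates
  withr::with_seed(11, {
    ps <- replicate(150, {
      h <- sample(bg, 25)
      s <- sample(bg, 40)
      a <- length(intersect(h, s))
      fisher_exact_p(a, 25 - a, 40 - a, 200 - 25 - 40 + a)
    })
    expect_lt(mean(ps < 0.05), 0.09)
  })
})

test_that("Kd fitting inverts noiseless data and flags degenerate series", {
  s <- simulate_binding_series(kd_nM = 100, bmax = 1,
                               concentrations_nM = c(20, 40, 80, 200, 400),
                               cv = 0, seed = 1)
  fit <- fit_kd(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd_nM - 100) / 100, 1e-6)

  flat <- tibble::tibble(conc_nM = c(20, 40, 80, 200, 400),
                         normalized = rep(1, 5))
  ffit <- fit_kd(flat)
  expect_false(ffit$converged)

  expect_error(fit_kd(tibble::tibble(conc_nM = c(1, 2),
                                     normalized = c(0.1, 0.2))),
               "3 distinct")
  expect_error(fit_kd(tibble::tibble(conc_nM = c(1, 2, 4),
                                     signal = c(0, 0, 0))), "all-zero")
})

test_that("Kd fitting is invariant to signal scale and equivariant in units", {
  s <- simulate_binding_series(kd_nM = 60, bmax = 0.9, cv = 0.05,
                               seed = 9)
  f1 <- fit_kd(s)
  f2 <- fit_kd(dplyr::mutate(dplyr::select(s, -"normalized"),
                             signal = signal * 10))
  expect_equal(f2$kd_nM, f1$kd_nM, tolerance = 1e-6)
  f3 <- fit_kd(dplyr::mutate(s, conc_nM = conc_nM * 10))
  expect_equal(f3$kd_nM, 10 * f1$kd_nM, tolerance = 1e-6)
})

test_that("Kd recovery under multiplicative noise stays within 10%", {
  series <- simulate_binding_series(kd_nM = 33, cv = 0.02, n_replicates = 25,
                                    seed = 13)
  errs <- vapply(split(series, series$replicate), function(d) {
    abs(fit_kd(d)$kd_nM - 33) / 33
  }, double(1))
  expect_lte(stats::median(errs), 0.10)
})

test_that("broom-style accessors and plots expose the fit", {
  s <- simulate_binding_series(kd_nM = 50, cv = 0, seed = 2)
  fit <- fit_kd(s)
  td <- tidy(fit)
  expect_equal(td$term, c("kd_nM", "bmax"))
  gl <- glance(fit)
  expect_equal(gl$n, 5L)
  expect_true(gl$converged)
  au <- augment(fit)
  expect_true(all(abs(au$.resid) < 1e-8))
  expect_s3_class(autoplot(fit), "ggplot")
})
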