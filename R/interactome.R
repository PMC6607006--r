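#' Clean an emPAI table
#'
#' Replaces the -1 non-detect sentinel with the lowest detected value across
#' the whole table, subtracts the bead-control emPAI from each condition,
#' and flags records whose bead signal exceeds the signal in *every*
#' condition as bead-dominant (such records are disregarded downstream).
#' Negative values other than the sentinel are an error. The operation is
#' idempotent: cleaning a cleaned table changes nothing.
#'
#' @param raw Tibble with `protein_id` (or `protein`) and columns `beads`,
#'   `LIF`, `RA` (any additional condition columns are preserved untouched).
#' @return Tibble: `protein_id`, `empai_beads`, `empai_LIF`, `empai_RA`
#'   (cleaned values), `adj_LIF`, `adj_RA` (bead-subtracted), `log2_ratio`
#'   (RA vs LIF on floored adjusted values), `discarded_bead_dominant`.
#' @export
clean_empai <- function(raw) {
  x <- tibble::as_tibble(raw)
  if ("protein" %in% names(x) && !"protein_id" %in% names(x)) {
    x <- dplyr::rename(x, protein_id = "protein")
  }
  nm <- c(beads = "beads", LIF = "LIF", RA = "RA")
  alt <- c(beads = "empai_beads", LIF = "empai_LIF", RA = "empai_RA")
  for (k in names(nm)) {
    if (!nm[k] %in% names(x) && alt[k] %in% names(x)) {
      names(x)[names(x) == alt[k]] <- nm[k]
    }
  }
  if (!all(c("protein_id", "beads", "LIF", "RA") %in% names(x))) {
    stopf("emPAI table needs protein_id, beads, LIF, RA columns")
  }
  vals <- cbind(x$beads, x$LIF, x$RA)
  if (any(vals < 0 & vals != -1)) {
    stopf("negative non-sentinel emPAI value")
  }
  detected <- vals[vals != -1]
  if (length(detected) == 0L) stopf("no detected emPAI values")
  floor_val <- min(detected)
  vals[vals == -1] <- floor_val
  adj_lif <- vals[, 2] - vals[, 1]
  adj_ra <- vals[, 3] - vals[, 1]
  # ratios are floored at the table's own detection floor, so flagging is
  # exactly equivariant under rescaling of the whole table
  out <- tibble::tibble(
    protein_id = x$protein_id,
    empai_beads = vals[, 1], empai_LIF = vals[, 2], empai_RA = vals[, 3],
    adj_LIF = adj_lif, adj_RA = adj_ra,
    log2_ratio = log2(pmax(adj_ra, floor_val) / pmax(adj_lif, floor_val)),
    discarded_bead_dominant = vals[, 1] > vals[, 2] & vals[, 1] > vals[, 3])
  attr(out, "floor_value") <- floor_val
  out
}

#' Flag condition-enriched proteins by emPAI fold change
#'
#' A protein is `enriched_RA` when its bead-subtracted RA emPAI exceeds
#' `fold` times its LIF value (adjusted values floored at the table's
#' detection floor so ratios stay finite), and symmetrically for
#' `enriched_LIF`. Bead-dominant records carry no enrichment flags.
#'
#' @param records Tibble from [clean_empai()].
#' @param fold Fold-change threshold (default 2).
#' @return `records` with logical `enriched_RA`, `enriched_LIF` columns.
#' @export
empai_enriched <- function(records, fold = 2) {
  lo <- attr(records, "floor_value") %||% 0.01
  ra <- pmax(records$adj_RA, lo)
  lif <- pmax(records$adj_LIF, lo)
  keep <- !records$discarded_bead_dominant
  records %>%
    dplyr::mutate(enriched_RA = keep & ra / lif > fold,
                  enriched_LIF = keep & lif / ra > fold)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT-format gene-set file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set over-representation of hit proteins
#'
#' For each gene set, tests the 2x2 table (hits in set, hits not in set,
#' background non-hits in set, background non-hits outside) with the shared
#' two-sided Fisher exact test and adjusts across sets with
#' Benjamini-Hochberg. Sets with no overlap with the background are skipped
#' with a warning.
#'
#' @param hits Character vector of hit protein/gene ids.
#' @param background Character vector of all detected ids.
#' @param gene_sets Named list of id vectors (e.g. from [read_gmt()]).
#' @return Tibble: `set`, `n_set`, `n_hits_in_set`, `p`, `q`.
#' @export
geneset_enrichment <- function(hits, background, gene_sets) {
  hits <- intersect(unique(hits), background)
  bg <- unique(background)
  keep <- vapply(gene_sets, function(s) length(intersect(s, bg)) > 0,
                 logical(1))
  if (any(!keep)) {
    warning(sprintf("%d gene set(s) without background overlap skipped",
                    sum(!keep)))
  }
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0L) {
    return(tibble::tibble(set = character(), n_set = integer(),
                          n_hits_in_set = integer(), p = double(),
                          q = double()))
  }
  res <- purrr::imap_dfr(gene_sets, function(s, nm) {
    s <- intersect(s, bg)
    a <- length(intersect(hits, s))
    b <- length(hits) - a
    cc <- length(s) - a
    d <- length(bg) - length(hits) - cc
    tibble::tibble(set = nm, n_set = length(s), n_hits_in_set = a,
                   p = fisher_exact_p(a, b, cc, d))
  })
  res$q <- bh_adjust(res$p)
  res
}

#' Fit a one-site equilibrium binding curve
#'
#' Least-squares fit of `y = Bmax * C / (Kd + C)` to normalized binding
#' signal, with positivity constraints, multi-start Levenberg-Marquardt
#' refinement (Kd started at the minimum, median and maximum concentration)
#' and the lowest-RSS solution returned. Bmax is left free because
#' normalization to the highest-concentration point does not guarantee
#' saturation there. Fits whose Kd collapses onto the lower boundary (a
#' flat, non-identifiable series) are flagged `converged = FALSE`.
#'
#' @param series Tibble with `conc_nM` and either `normalized` or `signal`
#'   (signal is normalized to the highest-concentration point first).
#' @return A `kd_fit` object: list with `kd_nM`, `bmax`, `rss`,
#'   `converged`, `data` and `fitted`.
#' @export
fit_kd <- function(series) {
  conc <- series$conc_nM
  if (length(unique(conc)) < 3L) stopf("need at least 3 distinct concentrations")
  y <- if ("normalized" %in% names(series)) {
    series$normalized
  } else {
    if (!"signal" %in% names(series)) stopf("series needs signal or normalized")
    if (all(series$signal == 0)) stopf("all-zero binding signal")
    series$signal / mean(series$signal[conc == max(conc)])
  }
  if (all(y == 0)) stopf("all-zero binding signal")

  lower_kd <- 1e-6 * min(conc)
  starts <- unique(c(min(conc), stats::median(conc), max(conc)))
  fits <- purrr::map(starts, function(k0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ bmax * conc / (kd + conc),
        start = list(kd = k0, bmax = max(y)),
        lower = c(kd = lower_kd, bmax = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0L) {
    return(structure(list(kd_nM = NA_real_, bmax = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          data = tibble::tibble(conc_nM = conc, y = y),
                          fitted = rep(NA_real_, length(y))),
                     class = "kd_fit"))
  }
  rss <- vapply(fits, stats::deviance, double(1))
  best <- fits[[which.min(rss)]]
  est <- stats::coef(best)
  at_boundary <- est[["kd"]] <= lower_kd * (1 + 1e-6)
  structure(list(
    kd_nM = est[["kd"]], bmax = est[["bmax"]], rss = min(rss),
    converged = isTRUE(best$convInfo$isConv) && !at_boundary,
    data = tibble::tibble(conc_nM = conc, y = y),
    fitted = stats::fitted(best)), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("One-site binding fit\n")
  cat(sprintf("  Kd   = %.4g nM\n  Bmax = %.4g\n  RSS  = %.4g\n  converged: %s\n",
              x$kd_nM, x$bmax, x$rss, x$converged))
  invisible(x)
}

#' Predicted binding curve for plotting
#'
#' @param fit A `kd_fit` object.
#' @param n Number of grid points.
#' @return Tibble `conc_nM`, `y` along a concentration grid.
#' @export
kd_curve <- function(fit, n = 100L) {
  grid <- seq(0, max(fit$data$conc_nM), length.out = n)
  tibble::tibble(conc_nM = grid,
                 y = fit$bmax * grid / (fit$kd_nM + grid))
}
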