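# Count matrices travel as tibbles with a `feature_id` column plus one
# column per sample; `attr(x, "normalized")` flags whether size-factor
# scaling has been applied.

count_matrix_id <- function(counts) {
  id <- intersect(c("feature_id", "transcript_id"), names(counts))
  if (length(id) == 0L) stopf("count matrix needs a feature_id column")
  id[1]
}

count_matrix_samples <- function(counts) {
  setdiff(names(counts), c("feature_id", "transcript_id"))
}

count_matrix_values <- function(counts) {
  m <- as.matrix(counts[, count_matrix_samples(counts), drop = FALSE])
  rownames(m) <- counts[[count_matrix_id(counts)]]
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors estimated as the median, over features with a
#' positive geometric mean, of the ratio of the feature's count to its
#' geometric mean across samples. Factors are rescaled to unit geometric
#' mean so they are comparable across runs; ratios between samples are
#' unaffected by the rescaling.
#'
#' @param counts Raw count tibble (`feature_id` + sample columns).
#' @return Tibble: `sample`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- count_matrix_values(counts)
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stopf(paste("no feature has nonzero counts in every sample;",
                "provide deeper data or use a pseudo-reference"))
  }
  s <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm[use]))
  })
  s <- s / exp(mean(log(s)))
  tibble::tibble(sample = colnames(m), size_factor = unname(s))
}

#' Apply size factors to a count matrix
#'
#' @param counts Raw count tibble.
#' @param sf Size-factor tibble from [size_factors()].
#' @return Normalized count tibble, flagged with `attr(., "normalized")`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  samples <- count_matrix_samples(counts)
  if (!setequal(sf$sample, samples)) stopf("size factors do not match samples")
  out <- counts
  for (s in samples) {
    out[[s]] <- counts[[s]] / sf$size_factor[sf$sample == s]
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Negative-binomial differential abundance test
#'
#' Median-of-ratios normalization followed by a per-feature two-group test
#' in the classic count-model mold: method-of-moments dispersion on
#' normalized counts, shrunk toward a gamma-family mean-dispersion trend
#' (prior df 10), then an exact conditional NB test (Robinson-Smyth style,
#' summing outcome probabilities no larger than the observed one) when both
#' groups have at most 5 samples, else a Wald test on the log scale.
#' Adjusted p-values are Benjamini-Hochberg.
#'
#' @param counts Raw count tibble (`feature_id` + sample columns).
#' @param groups Named character/factor vector mapping every sample column
#'   to one of two group labels.
#' @param sf Optional precomputed size factors.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return A `tsrna_de` tibble: `feature_id`, `baseMeanA`, `baseMeanB`,
#'   `log2FC` (B vs A), `pval`, `padj`; attributes `method`, `groups`.
#' @export
nb_test <- function(counts, groups, sf = NULL, prior_df = 10) {
  m <- count_matrix_values(counts)
  samples <- colnames(m)
  if (!all(samples %in% names(groups))) {
    stopf("groups must name every sample column")
  }
  g <- factor(unname(groups[samples]))
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  if (any(colSums(m) == 0)) stopf("a sample has an all-zero library")
  lvls <- levels(g)
  idxA <- which(g == lvls[1]); idxB <- which(g == lvls[2])
  nA <- length(idxA); nB <- length(idxB)

  if (is.null(sf)) sf <- size_factors(counts)
  sfv <- sf$size_factor[match(samples, sf$sample)]
  z <- sweep(m, 2, sfv, "/")

  mu <- rowMeans(z)
  muA <- rowMeans(z[, idxA, drop = FALSE])
  muB <- rowMeans(z[, idxB, drop = FALSE])

  # method-of-moments dispersion from pooled within-group variance
  vw <- function(idx) {
    if (length(idx) < 2L) return(rep(NA_real_, nrow(z)))
    apply(z[, idx, drop = FALSE], 1, stats::var)
  }
  vA <- vw(idxA); vB <- vw(idxB)
  dfA <- max(nA - 1L, 0L); dfB <- max(nB - 1L, 0L)
  resid_df <- dfA + dfB
  if (resid_df == 0L) stopf("at least one group needs replicates")
  pooled_var <- (ifelse(is.na(vA), 0, vA) * dfA +
                 ifelse(is.na(vB), 0, vB) * dfB) / resid_df
  mu_w <- (muA * nA + muB * nB) / (nA + nB)
  disp_raw <- ifelse(mu_w > 0, (pooled_var - mu_w) / mu_w^2, NA_real_)

  disp_trend <- fit_dispersion_trend(disp_raw, mu_w)
  disp <- (resid_df * pmax(disp_raw, 0) + prior_df * disp_trend) /
    (resid_df + prior_df)
  disp[is.na(disp)] <- disp_trend[is.na(disp)]
  disp <- pmax(disp, 1e-8)

  exact <- nA <= 5L && nB <= 5L
  pseudo <- round(z)
  pval <- vapply(seq_len(nrow(m)), function(f) {
    if (exact) {
      nb_exact_p(sum(pseudo[f, idxA]), sum(pseudo[f, idxB]), nA, nB, disp[f])
    } else {
      nb_wald_p(z[f, idxA], z[f, idxB], sfv[idxA], sfv[idxB], disp[f])
    }
  }, double(1))

  # fold change for reporting: 0.5 pseudo-count when a group mean is zero
  eps <- ifelse(muA == 0 | muB == 0, 0.5, 0)
  log2fc <- log2((muB + eps) / (muA + eps))

  out <- tibble::tibble(feature_id = rownames(m), baseMeanA = unname(muA),
                        baseMeanB = unname(muB), log2FC = unname(log2fc),
                        pval = unname(pval), padj = bh_adjust(unname(pval)))
  attr(out, "method") <- if (exact) "nb-exact-conditional" else "nb-wald"
  attr(out, "groups") <- stats::setNames(lvls, c("A", "B"))
  class(out) <- c("tsrna_de", class(out))
  out
}

# Gamma-family regression of (truncated) raw dispersion on 1/mean,
# identity link: disp(mu) = a0 + a1/mu. Falls back to the median positive
# dispersion if the GLM cannot be fitted.
fit_dispersion_trend <- function(disp_raw, mu) {
  ok <- is.finite(disp_raw) & is.finite(mu) & mu > 0
  y <- pmax(disp_raw[ok], 1e-8)
  x <- 1 / mu[ok]
  fallback <- stats::median(y[y > 1e-8]) %||% 0.1
  if (length(fallback) == 0L || !is.finite(fallback)) fallback <- 0.1
  trend <- rep(fallback, length(disp_raw))
  if (length(y) >= 10L) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ x, family = stats::Gamma(link = "identity"),
                                  start = c(fallback, 0))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      pred <- co[1] + co[2] / pmax(mu, 1e-8)
      trend <- pmax(pred, 1e-8)
    }
  }
  trend
}

# Two-sided exact conditional NB test: given group sums sA, sB over nA and
# nB samples at common per-sample mean and dispersion phi, sum the
# conditional probabilities of all splits of s = sA + sB whose point
# probability is at most the observed one (1e-7 relative slack).
nb_exact_p <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  m <- s / (nA + nB)
  a <- 0:s
  logp <- stats::dnbinom(a, mu = nA * m, size = nA / phi, log = TRUE) +
    stats::dnbinom(s - a, mu = nB * m, size = nB / phi, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[sA + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Wald test on the log link with delta-method variance of group log-means.
nb_wald_p <- function(zA, zB, sfA, sfB, phi) {
  mA <- mean(zA); mB <- mean(zB)
  if (mA == 0 && mB == 0) return(1)
  mA <- max(mA, 0.5); mB <- max(mB, 0.5)
  vA <- sum(mA / sfA + phi * mA^2) / length(zA)^2
  vB <- sum(mB / sfB + phi * mB^2) / length(zB)^2
  se <- sqrt(vA / mA^2 + vB / mB^2)
  stat <- (log(mB) - log(mA)) / se
  2 * stats::pnorm(-abs(stat))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values (step-up with monotonicity enforcement).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @return `min(1, m * p)` elementwise, m = number of tests.
#' @export
bonferroni_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "bonferroni")
}
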