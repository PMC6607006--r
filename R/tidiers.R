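#' Tidy a one-site binding fit
#'
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(term = c("kd_nM", "bmax"),
                 estimate = c(x$kd_nM, x$bmax))
}

#' One-row summary of a one-site binding fit
#'
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @return Tibble with `kd_nM`, `bmax`, `rss`, `n`, `converged`.
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(kd_nM = x$kd_nM, bmax = x$bmax, rss = x$rss,
                 n = nrow(x$data), converged = x$converged)
}

#' Observed data with fitted values for a binding fit
#'
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @return The fit's data with `.fitted` and `.resid` columns.
#' @export
augment.kd_fit <- function(x, ...) {
  x$data %>%
    dplyr::mutate(.fitted = x$fitted, .resid = .data$y - x$fitted)
}

#' One-row summary of a differential-abundance result
#'
#' @param x A `tsrna_de` tibble from [nb_test()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @param ... Unused.
#' @return Tibble with feature counts and the test method.
#' @export
glance.tsrna_de <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$padj < alpha, na.rm = TRUE),
    method = attr(x, "method") %||% NA_character_)
}
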