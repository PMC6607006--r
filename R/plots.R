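#' Plot per-base coverage profiles
#'
#' Line plot of the per-base coverage fraction along each cluster, optionally
#' marking the anticodon position -- the visual used to show that 5'-tsRNAs
#' start at the tRNA 5' end and stop short of the anticodon loop.
#'
#' @param object A `tsrna_coverage` tibble from [per_base_coverage()].
#' @param clusters Optional cluster tibble; when given, the anticodon start
#'   is drawn as a dashed line.
#' @param top_n Show only the `top_n` clusters with the highest total
#'   coverage.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsrna_coverage <- function(object, clusters = NULL, top_n = 6L, ...) {
  totals <- object %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(total = sum(.data$coverage), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$total))
  keep <- utils::head(totals$cluster_id, top_n)
  df <- object %>% dplyr::filter(.data$cluster_id %in% keep)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$coverage)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~cluster_id, scales = "free_x") +
    ggplot2::labs(x = "tRNA position (nt)", y = "per-base coverage fraction") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    ac <- clusters %>%
      dplyr::filter(.data$cluster_id %in% keep) %>%
      dplyr::select("cluster_id", "anticodon_start")
    p <- p + ggplot2::geom_vline(data = ac,
                                 ggplot2::aes(xintercept = .data$anticodon_start),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot the tRNA fraction of genome-mapped reads by read length
#'
#' @param fraction_table Tibble from [trna_fraction_by_length()].
#' @return A ggplot object.
#' @export
plot_trna_fraction <- function(fraction_table) {
  ggplot2::ggplot(fraction_table,
                  ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "read length (nt)",
                  y = "tRNA-mapped / genome-mapped reads") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential-abundance result
#'
#' @param object A `tsrna_de` tibble from [nb_test()].
#' @param alpha Adjusted-p threshold colouring significant features.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsrna_de <- function(object, alpha = 0.05, ...) {
  df <- object %>%
    dplyr::mutate(mean_expr = (.data$baseMeanA + .data$baseMeanB) / 2,
                  sig = .data$padj < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_expr, y = .data$log2FC,
                                   colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("padj < %.2g", alpha)) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Scatter plot of pulldown enrichment between cell states
#'
#' log2 tsRNA/scramble fold change in LIF vs RA, coloured by allocated
#' state.
#'
#' @param records Tibble from [pulldown_analysis()].
#' @return A ggplot object.
#' @export
plot_pulldown_states <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = log2(.data$fc_LIF), y = log2(.data$fc_RA),
                               colour = .data$state)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "log2 FC (tsRNA/scr, LIF)",
                  y = "log2 FC (tsRNA/scr, RA)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted binding curve
#'
#' @param object A `kd_fit` object from [fit_kd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_nM, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = kd_curve(object),
                       ggplot2::aes(y = .data$y), colour = "firebrick") +
    ggplot2::labs(x = "protein concentration (nM)",
                  y = "fraction bound (normalized)",
                  subtitle = sprintf("Kd = %.3g nM", object$kd_nM)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
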