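#' Real-versus-synthetic summary-statistic panels
#'
#' Scatter plots of the gene-wise statistics (mean, variance, cv, zero
#' proportion) of the synthetic matrix against the real one; mean and
#' variance are shown on the `log10(1 + x)` scale. Points on the diagonal
#' indicate perfect preservation of that statistic.
#'
#' @param object An `eval_report` from [compare_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  rs <- object$real_stats$gene_stats
  ss <- object$synth_stats$gene_stats
  long <- dplyr::bind_rows(
    tibble::tibble(statistic = "log10(1 + mean)",
                   real = log10(1 + rs$mean),
                   synthetic = log10(1 + ss$mean)),
    tibble::tibble(statistic = "log10(1 + variance)",
                   real = log10(1 + rs$var),
                   synthetic = log10(1 + ss$var)),
    tibble::tibble(statistic = "cv", real = rs$cv, synthetic = ss$cv),
    tibble::tibble(statistic = "zero proportion",
                   real = rs$zero_prop, synthetic = ss$zero_prop)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$real, y = .data$synthetic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "real data", y = "synthetic data") +
    ggplot2::theme_bw()
}

#' Heatmap of a gene-gene correlation matrix
#'
#' @param R Correlation matrix, e.g. from [correlation_matrix()]; the
#'   `"order"` attribute (complete-linkage clustering order), when present,
#'   arranges the genes.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(R, title = NULL) {
  ord <- attr(R, "order") %||% seq_len(nrow(R))
  R <- R[ord, ord]
  df <- tibble::as_tibble(as.table(R), .name_repair = ~c("g1", "g2", "corr"))
  df$g1 <- factor(df$g1, levels = rownames(R))
  df$g2 <- factor(df$g2, levels = colnames(R))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g1, y = .data$g2,
                                   fill = .data$corr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "corr", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Correlation-recovery MSE curves
#'
#' Mean recovery error of the copula correlation as a function of the
#' number of cells, one curve per gene-panel size, with reference lines at
#' the 0.09 / 0.04 / 0.01 quality levels (roughly ±0.3 / ±0.2 / ±0.1 on
#' the correlation scale).
#'
#' @param recovery Tibble from [correlation_recovery_experiment()].
#' @return A ggplot object.
#' @export
plot_recovery_curve <- function(recovery) {
  agg <- dplyr::summarise(dplyr::group_by(recovery, .data$n, .data$p),
                          mse = mean(.data$mse), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$n, y = .data$mse,
                                    colour = factor(.data$p))) +
    ggplot2::geom_hline(yintercept = c(0.09, 0.04, 0.01), linetype = 3,
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of cells (n)", y = "mean squared error",
                  colour = "genes (p)") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
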