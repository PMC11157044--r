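#' Plot methods for rich-club results
#'
#' `autoplot.mlfcn_richclub()` shows the distribution of each rich-club
#' metric split by tissue class.  `plot_core_assignment()` draws the binary
#' core-membership raster (ROIs by temporal layers) that underlies the
#' temporal metrics.  `plot_icc()` shows per-unit ICC values against the
#' tissue-specific reliability benchmarks (0.6 GM / 0.5 WM, 0.8
#' significant).
#'
#' @param object A `mlfcn_richclub`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mlfcn_richclub <- function(object, ...) {
  tidy(object) |>
    filter(.data$metric %in% c("tc", "ts", "lf", "jf")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$tissue, y = .data$value,
                                 fill = .data$tissue)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = "Dynamic rich-club metrics by tissue class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.mlfcn_richclub
#' @param metrics A `mlfcn_richclub` (its `core` attribute is used) or a
#'   binary core-assignment matrix.
#' @export
plot_core_assignment <- function(metrics) {
  r <- if (inherits(metrics, "mlfcn_richclub")) attr(metrics, "core") else metrics
  r <- unclass(r)
  df <- tidyr::expand_grid(roi = seq_len(nrow(r)), layer = seq_len(ncol(r)))
  df$core <- r[cbind(df$roi, df$layer)] == 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$roi,
                                   fill = .data$core)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "temporal layer", y = "ROI index",
                  title = "Rich-club core membership over time") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.mlfcn_richclub
#' @param icc_table Result of [icc_analysis()].
#' @export
plot_icc <- function(icc_table) {
  ggplot2::ggplot(icc_table,
                  ggplot2::aes(x = .data$unit, y = .data$icc,
                               colour = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(0.5, 0.6), linetype = "dotted") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "ICC",
                  title = "Test-retest reliability by unit and metric") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
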