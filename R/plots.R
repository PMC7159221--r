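# ggplot2 displays for the main result types.

#' Plot risk-standardized rate distributions
#'
#' Histograms of per-hospital risk-standardized readmission rates,
#' faceted by model.
#'
#' @param rsrr An RSRR tibble (rows from one or more models).
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_rsrr_distribution <- function(rsrr, bins = 30) {
  ggplot2::ggplot(rsrr, ggplot2::aes(x = .data$rsrr)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~ .data$model_kind, scales = "free_y") +
    ggplot2::labs(x = "risk-standardized readmission rate",
                  y = "hospitals") +
    ggplot2::theme_minimal()
}

#' Plot per-model test AUCs
#'
#' @param report An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(report, ...) {
  ggplot2::ggplot(report$auc,
                  ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_point(alpha = 0.6, position = ggplot2::position_jitter(
      width = 0.05, height = 0, seed = 1
    )) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95,
                          size = 10, colour = "red3") +
    ggplot2::labs(x = NULL, y = "test-set AUC") +
    ggplot2::theme_minimal()
}

#' Plot a reclassification table
#'
#' Tile display of the 3x3 hospital-group cross-tabulation.
#'
#' @param table A `reclassification_table`.
#' @return A ggplot object.
#' @export
plot_reclassification <- function(table) {
  m <- unclass(table)
  attr(m, "total") <- NULL
  df <- as.data.frame(as.table(m))
  names(df) <- c("model_a", "model_b", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_b, y = .data$model_a,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$model_a))) +
    ggplot2::labs(x = "model B group", y = "model A group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
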