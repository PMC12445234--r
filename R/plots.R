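#' Histogram of composite behavior scores by group
#'
#' @param scores Score tibble from [composite_scores()] (optionally
#'   classified).
#' @param score_col Score column to plot.
#' @param binwidth Histogram bin width (scores are small integers; 2 mirrors
#'   the usual presentation).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, score_col = "total", binwidth = 2) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[[score_col]],
                                       fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "composite anxiety-like behavior score",
                  y = "animals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Startle threshold curve plot
#'
#' @param curve Tibble from [threshold_curve()].
#' @return A ggplot object.
#' @export
plot_threshold_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$intensity_db,
                                      y = .data$mean_amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus intensity (dB)",
                  y = "mean startle amplitude") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `cbc_de` from [de_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbc_de
#' @export
autoplot.cbc_de <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fold_change,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(title = attr(object, "contrast"),
                  x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
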