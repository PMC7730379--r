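# ggplot2 views of a reliability report, mirroring the tool's three result
# tabs: regression, quantile classification, and the max-n scatter.

#' Plot reliability-report surfaces
#'
#' `plot_r2()` draws the R^2-vs-number-of-samples curve, `plot_accuracy()`
#' the tertile/quartile classification curves, and `plot_scatter()` the
#' internal-dose AUC against the maximum-size pooled concentration (log-log).
#' `autoplot()` arranges all three (with patchwork when installed, otherwise
#' returning the R^2 panel).
#'
#' @param report A `reliability_report` from [run_scenario()].
#' @return A ggplot object.
#' @export
plot_r2 <- function(report) {
  ggplot2::ggplot(report$curves, ggplot2::aes(x = .data$n, y = .data$r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Number of pooled urine samples",
                  y = expression(R^2),
                  title = "Internal exposure (AUC) vs. urinary levels") +
    ggplot2::theme_minimal()
}

#' @rdname plot_r2
#' @export
plot_accuracy <- function(report) {
  long <- tidyr::pivot_longer(
    report$curves, c("tertile_accuracy", "quartile_accuracy"),
    names_to = "quantile", values_to = "accuracy")
  long$quantile <- ifelse(long$quantile == "tertile_accuracy",
                          "Tertiles", "Quartiles")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$accuracy,
                                     colour = .data$quantile)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Number of pooled urine samples",
                  y = "Correctly classified (%)", colour = NULL,
                  title = "Quantile classification accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_r2
#' @export
plot_scatter <- function(report) {
  nmax <- max(report$curves$n)
  ggplot2::ggplot(report$scatter,
                  ggplot2::aes(x = .data$pooled, y = .data$auc)) +
    ggplot2::geom_point(alpha = 0.3, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("Mean urinary concentration (%d samples)", nmax),
                  y = "Internal exposure (AUC)",
                  title = "AUC vs. pooled urinary concentration") +
    ggplot2::theme_minimal()
}

#' @rdname plot_r2
#' @param object A `reliability_report`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot reliability_report
#' @export
autoplot.reliability_report <- function(object, ...) {
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(plot_r2(object), plot_accuracy(object),
                          plot_scatter(object), ncol = 2)
  } else {
    plot_r2(object)
  }
}

#' @export
ggplot2::autoplot
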