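#' Plot the time-activity curves of a dynamic study
#'
#' @param object A `dynamic_study`.
#' @param regions Regions to draw; default blood plus three representative
#'   segments and the extracardiac curve when present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dynamic_study <- function(object, regions = NULL, ...) {
  long <- tac_long(object)
  if (is.null(regions)) {
    regions <- intersect(c("blood", "seg01", "seg04", "seg17", "extracardiac"),
                         unique(long$region))
  }
  long <- dplyr::filter(long, .data$region %in% regions)
  ggplot2::ggplot(long, ggplot2::aes(.data$t_mid_s, .data$value,
                                     colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "activity (a.u.)",
                  title = sprintf("Dynamic study (%s)", object$condition),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of two paired measurement series
#'
#' Differences against pair means, with the mean difference and 95% limits
#' of agreement as horizontal lines.
#'
#' @param a,b Numeric vectors of equal length.
#' @param label Optional parameter label for the title.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(a, b, label = NULL) {
  check_paired(a, b)
  ba <- bland_altman(a, b)
  df <- tibble::tibble(m = (a + b) / 2, d = a - b)
  ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "pair mean", y = "difference",
                  title = label %||% "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Plot inter-operator correlations by model and region
#'
#' @param object An `experiment_result`.
#' @param parameter Which parameter to show (default `"mfr"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_result <- function(object, parameter = "mfr", ...) {
  d <- dplyr::filter(object$report$agreement, .data$parameter == !!parameter)
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$r_spearman,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::coord_cartesian(ylim = c(min(0.5, min(d$r_spearman)), 1)) +
    ggplot2::labs(x = NULL, y = "Spearman r",
                  title = sprintf("Processing repeatability (%s)", parameter),
                  fill = "model") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
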