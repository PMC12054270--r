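#' Plot simulation-study results
#'
#' Bar panels of percent bias or coverage by method, faceted by parameter,
#' mirroring the usual presentation of sensitivity analyses over the
#' ignorability grid. The 95% reference line is drawn on coverage panels.
#'
#' @param object An `mi_results` tibble.
#' @param metric `"bias"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_results <- function(object, metric = c("bias", "coverage"), ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object)
  ycol <- if (metric == "bias") "percent_bias" else "coverage"
  ylab <- if (metric == "bias") "Percent bias (%)" else "Coverage (%)"
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$method, y = .data[[ycol]],
    fill = ifelse(is.na(.data$structure), "comparator", .data$structure))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = NULL, y = ylab, fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (metric == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 95, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot composite-score trajectories
#'
#' Mean composite score per time point with a ribbon of +/- one standard
#' deviation, from a (possibly incomplete) panel.
#'
#' @param panel A `component_panel`.
#' @param criteria Composite criteria.
#' @return A ggplot object.
#' @export
plot_composite_trajectory <- function(panel, criteria = ideal_criteria()) {
  comp <- as_tibble(build_composite(panel, criteria)) %>%
    filter(!is.na(.data$score)) %>%
    group_by(.data$years) %>%
    summarise(mean = mean(.data$score), sd = sd(.data$score),
              .groups = "drop")
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$years, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Years of follow-up", y = "Composite score (0-5)") +
    ggplot2::theme_bw()
}
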