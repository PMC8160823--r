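#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stability-selection frequencies
#'
#' Horizontal bars of per-variable selection frequencies with the
#' selection threshold drawn as a dashed line.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_report <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frequency,
    y = stats::reorder(.data$variable, .data$frequency),
    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = cfg$selection_threshold,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "selection frequency", y = NULL,
                  title = paste("Stability selection:", attr(object, "endpoint")),
                  fill = paste0("> ", cfg$selection_threshold)) +
    ggplot2::theme_minimal()
}

#' Forest plot of pooled odds ratios
#'
#' @param object An `svystab_analysis`.
#' @param ... Unused.
#' @return A ggplot of ORs with 95% intervals per disability and model.
#' @export
autoplot.svystab_analysis <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(
    x = .data$or, y = .data$disability, color = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Imputation chain trace plot
#'
#' Imputed-category frequencies per chain iteration, one line per stream,
#' faceted by variable and level; flat, well-mixed traces indicate
#' convergence of the chained equations.
#'
#' @param object An `imputation_set`.
#' @param ... Unused.
#' @return A ggplot (empty data yield an empty plot).
#' @export
autoplot.imputation_set <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(
    x = .data$iteration, y = .data$prop,
    group = .data$stream, color = factor(.data$stream))) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~ .data$variable + .data$level, scales = "free_y") +
    ggplot2::labs(x = "chain iteration", y = "imputed-category frequency") +
    ggplot2::theme_minimal()
}
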