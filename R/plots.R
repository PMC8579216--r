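#' Plot a feature-outcome association table
#'
#' Dot plot of adjusted Spearman coefficients per feature, faceted by
#' outcome, with open circles for the unadjusted coefficients and a dashed
#' zero line — the visual analogue of the association tables of a sensing
#' study.
#'
#' @param object A `digiphen_associations` table from [associate_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.digiphen_associations <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(x = .data$r_unadj), shape = 1,
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p < 0.05), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey30"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "adjusted Spearman r (open: unadjusted)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot daily feature trajectories
#'
#' Line plot of a daily feature over the study window for a sample of
#' participants, useful for eyeballing extraction output and simulated
#' behavior.
#'
#' @param daily Daily feature table (from [extract_features()] or a pipeline
#'   run).
#' @param feature Feature column name to plot (default `"time_sedentary_h"`).
#' @param max_participants Cap on the number of participants drawn
#'   (default 20).
#' @return A ggplot object.
#' @export
plot_daily_feature <- function(daily, feature = "time_sedentary_h",
                               max_participants = 20) {
  ids <- utils::head(unique(daily$participant_id), max_participants)
  d <- daily[daily$participant_id %in% ids, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data[[feature]],
                                  group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' Plot the retention flow of a cohort
#'
#' Bar chart of the exclusion accounting: enrolled, each exclusion reason in
#' attribution order, and retained.
#'
#' @param retention Result of [apply_retention_filters()].
#' @return A ggplot object.
#' @export
plot_retention <- function(retention) {
  ex <- attr(retention, "exclusions")
  d <- tibble::tibble(
    stage = factor(c("enrolled", names(ex), "retained"),
                   levels = c("enrolled", names(ex), "retained")),
    n = c(nrow(retention), unname(ex), sum(retention$retained)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "participants") +
    ggplot2::theme_minimal()
}
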