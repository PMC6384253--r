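#' Plot the ranked candidate scores
#'
#' Dot plot of overall priority score (log10 scale) against rank, labelled
#' by gene where available and coloured by region class — the at-a-glance
#' view of how sharply the top candidate separates from the rest.
#'
#' @param object A `pedscreen_result` from [run_prioritize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pedscreen_result
#' @export
autoplot.pedscreen_result <- function(object, ...) {
  ranked <- object$ranked
  if (nrow(ranked) == 0L) {
    stop("no ranked candidates to plot", call. = FALSE)
  }
  ggplot2::ggplot(ranked,
                  ggplot2::aes(x = .data$rank, y = .data$overall,
                               colour = .data$region)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Rank", y = "Overall priority score",
                  colour = "Region") +
    ggplot2::theme_minimal()
}

#' Plot the filter-cascade attrition
#'
#' Bar chart of variant counts entering and surviving each filter stage,
#' mirroring the staged-count narrative of a prioritization run.
#'
#' @param result A `pedscreen_result` from [run_prioritize()].
#' @return A ggplot object.
#' @export
plot_filter_cascade <- function(result) {
  counts <- glance(result)
  counts$stage <- factor(counts$stage, levels = counts$stage)
  long <- tidyr::pivot_longer(counts, c("input", "output"),
                              names_to = "side", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Filter stage", y = "Variants", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot expression groups with mean and SD
#'
#' Jittered raw measurements per group overlaid with the group mean and
#' one-SD error bars, the usual presentation of a small expression
#' comparison.
#'
#' @param data Raw-layout expression tibble (`group`, `value` columns).
#' @return A ggplot object.
#' @export
plot_expression_groups <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  summ <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = "Expression") +
    ggplot2::theme_minimal()
}
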