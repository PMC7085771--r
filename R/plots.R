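#' Plot class-average behaviour streams
#'
#' Hourly mean minutes per behaviour for healthy vs sick animals, one panel
#' per stream - the visual check that the generator (or a real cohort)
#' carries the class contrast the nearest-centroid stage relies on.
#'
#' @param cohort An `sck_cohort`.
#' @param time_frame `"post"` (default) or `"pre"`.
#' @return A ggplot object.
#' @export
plot_stream_means <- function(cohort, time_frame = c("post", "pre")) {
  time_frame <- match.arg(time_frame)
  series <- if (time_frame == "pre") cohort$series_pre else cohort$series_post
  df <- series |>
    dplyr::left_join(cohort$labels, by = "animal_id") |>
    tidyr::pivot_longer(dplyr::all_of(.stream_names),
                        names_to = "stream", values_to = "minutes") |>
    dplyr::group_by(.data$stream, .data$label, .data$hour) |>
    dplyr::summarise(minutes = mean(.data$minutes), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$minutes,
                                   colour = .data$label,
                                   linetype = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stream, scales = "free_y") +
    ggplot2::labs(x = paste0("hour of ", time_frame, "-partum week"),
                  y = "minutes per hour", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trained weight matrix
#'
#' Heatmap of the sign matrix (or any blend): +1 entries mark hour pairs
#' whose absolute differences separate the class means, -1 pairs that do
#' not.
#'
#' @param object A `weight_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$weight <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#e08214", midpoint = 0) +
    ggplot2::labs(x = "hour j", y = "hour i", fill = "g(i,j)") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' `what = "measures"` shows the confusion-matrix measure battery;
#' `what = "selection"` the per-feature selection counts across folds.
#'
#' @param object An `sck_report`.
#' @param what `"measures"` or `"selection"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sck_report <- function(object, what = c("measures", "selection"), ...) {
  what <- match.arg(what)
  if (what == "measures") {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$measure, .data$value)) +
      ggplot2::geom_col(fill = "#4477aa") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- selection_frequencies(object)
    df$feature <- factor(df$feature, rev(df$feature))
    ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$times_chosen)) +
      ggplot2::geom_col(fill = "#4477aa") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "folds in which the feature was chosen") +
      ggplot2::theme_minimal()
  }
}
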