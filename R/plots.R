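#' Plot a gaze trace with detected events
#'
#' Diagnostic plot of a recording on the unwrapped wall surface: the raw
#' sample path, the AOI layout, and (optionally) detected fixation
#' centroids sized by duration.
#'
#' @param recording A [gaze_recording()].
#' @param layout Optional [aoi_layout()] drawn behind the trace.
#' @param fixations Optional fixation tibble overlaid as points.
#' @return A ggplot object.
#' @export
plot_scanpath <- function(recording, layout = NULL, fixations = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(layout)) {
    v <- layout$vertices
    p <- p + ggplot2::geom_polygon(
      data = v,
      ggplot2::aes(x = .data$az_deg, y = .data$el_deg, group = .data$aoi_id,
                   linetype = .data$kind),
      fill = NA, colour = "grey60"
    )
  }
  rec <- tibble::as_tibble(recording)
  p <- p + ggplot2::geom_path(
    data = rec[rec$valid, , drop = FALSE],
    ggplot2::aes(x = .data$az_deg, y = .data$el_deg),
    colour = "steelblue", alpha = 0.6, linewidth = 0.3
  )
  if (!is.null(fixations) && nrow(fixations) > 0) {
    p <- p + ggplot2::geom_point(
      data = fixations,
      ggplot2::aes(x = .data$az_deg, y = .data$el_deg,
                   size = .data$duration_s),
      colour = "firebrick", alpha = 0.7
    )
  }
  p + ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                    size = "fixation (s)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scanpath
#' @param object A [gaze_recording()].
#' @param ... Passed to [plot_scanpath()].
#' @export
autoplot.gaze_recording <- function(object, ...) {
  plot_scanpath(object, ...)
}

#' Plot group-by-phase metric summaries
#'
#' Means and standard errors of each metric by group and phase: the
#' standard view of a pre/post training contrast.
#'
#' @param object A `study_dataset` tibble.
#' @param metrics Metric columns to show (default: all numeric metrics).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_dataset <- function(object, metrics = NULL, ...) {
  id_cols <- c("participant", "group", "pool", "phase")
  if (is.null(metrics)) {
    metrics <- setdiff(names(object)[vapply(object, is.numeric, logical(1))],
                       id_cols)
  }
  long <- tidyr::pivot_longer(object, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  summ <- long |>
    dplyr::group_by(.data$group, .data$phase, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     se = stats::sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$value))),
                     .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$phase, y = .data$mean,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.1, position = ggplot2::position_dodge(0.2)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- SE") +
    ggplot2::theme_minimal()
}

#' Plot the cell means behind a mixed-ANCOVA fit
#'
#' @param object A `gaze_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_anova <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, cols = c("pre", "post"),
                              names_to = "phase", values_to = "value")
  long$phase <- factor(long$phase, levels = c("pre", "post"))
  summ <- long |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$phase, y = .data$mean,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se), width = 0.1
    ) +
    ggplot2::labs(x = NULL, y = object$dv) +
    ggplot2::theme_minimal()
}
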