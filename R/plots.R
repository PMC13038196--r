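#' Plot comet tracks
#'
#' Track overlay in image coordinates (row axis reversed so the plot
#' matches the image orientation), coloured by track id.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_px`, `y_px`.
#' @param image_shape optional `c(rows, cols)` to fix the panel limits.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, image_shape = NULL) {
  p <- ggplot2::ggplot(as_tibble(tracks),
                       ggplot2::aes(.data$x_px, .data$y_px,
                                    group = .data$track_id,
                                    colour = factor(.data$track_id))) +
    ggplot2::geom_path(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(image_shape))
    p <- p + ggplot2::scale_y_reverse(limits = c(image_shape[1] - 1, 0)) +
      ggplot2::xlim(0, image_shape[2] - 1)
  else p <- p + ggplot2::scale_y_reverse()
  p
}

#' Compare per-track kinematics across conditions
#'
#' Boxplots (with jittered points) of the per-track statistics for two or
#' more conditions, faceted by statistic -- the panel layout used to
#' contrast early unidirectional and late bidirectional growth regimes.
#'
#' @param kinematics named list of per-track kinematics tibbles (from
#'   [track_kinematics()] or [tidy.movie_summary()]), one per condition.
#' @return A ggplot.
#' @export
plot_kinematics_comparison <- function(kinematics) {
  stopifnot(is.list(kinematics), !is.null(names(kinematics)))
  df <- dplyr::bind_rows(kinematics, .id = "condition")
  long <- tidyr::pivot_longer(
    df, c("velocity_um_min", "angle_fluctuation_deg", "straightness"),
    names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long[!is.na(long$value), ],
                  ggplot2::aes(.data$condition, .data$value,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.4) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Rose diagram of movement angles
#'
#' Circular histogram of per-track net movement angles; coherent
#' unidirectional growth shows one lobe, bundled bidirectional growth two
#' opposed lobes.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param binwidth bin width in degrees.
#' @return A ggplot.
#' @export
plot_angle_rose <- function(angles_deg, binwidth = 15) {
  df <- tibble(angle = angles_deg[!is.na(angles_deg)] %% 360)
  ggplot2::ggplot(df, ggplot2::aes(.data$angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey20",
                            linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = NULL, y = "tracks") +
    ggplot2::theme_minimal()
}
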