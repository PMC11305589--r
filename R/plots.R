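#' Plot a communication trajectory
#'
#' Draws the trajectory segments in the first quadrant of the (x, y) plane,
#' where x = r cos(theta) and y = r sin(theta). Segments bridging across
#' silent rows are dashed.
#'
#' @param object A [polar_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polar_trajectory <- function(object, ...) {
  seg <- trajectory_segments(object)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linetype = .data$bridged),
      alpha = 0.4, show.legend = FALSE
    ) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r cos(theta)", y = "r sin(theta)",
                  title = "Communication trajectory")
}

#' Plot the transition series
#'
#' One panel per series (I, L, L_R, S) against the transition index.
#'
#' @param object A [transition_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = c("I", "L", "L_R", "S"),
                              names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = c("I", "L", "L_R", "S"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "transition", y = NULL)
}

#' Radar chart of normalised measures
#'
#' Polar plot of the per-item normalised values, one polygon per community.
#'
#' @param object A [normalize_radar()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radar_profile <- function(object, ...) {
  df <- as_tibble(object)
  # close the polygon by repeating the first item per community
  first_item <- df$item[1]
  closing <- df[df$item == first_item, , drop = FALSE]
  df <- bind_rows(df, closing)
  df$item <- factor(df$item, levels = unique(object$item))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$normalized,
                                   group = .data$community,
                                   colour = .data$community)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "normalised value")
}
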