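#' Posture plot of root centerlines
#'
#' Draws every root with its basal point translated to the origin (the
#' conventional presentation for wavy-root cohorts), optionally coloured by
#' the smoothed curvature index on a shared scale.
#'
#' @param profiles Per-point tibble from [measure_collection()] /
#'   [profile_table()] (columns root_id, group, x, y, kappa_smooth, valid).
#' @param color_ci Colour points by `kappa_smooth` (default FALSE).
#' @param vmax Upper colour-scale limit, cm^-1 (default 50, the exceedance
#'   threshold); values above are squashed to `vmax`.
#' @return A ggplot object.
#' @export
plot_posture <- function(profiles, color_ci = FALSE, vmax = 50) {
  stopifnot(is.data.frame(profiles),
            all(c("root_id", "x", "y") %in% names(profiles)))
  df <- dplyr::group_by(profiles, .data$root_id)
  df <- dplyr::mutate(df, x0 = .data$x - dplyr::first(.data$x),
                      y0 = .data$y - dplyr::first(.data$y))
  df <- dplyr::ungroup(df)
  has_group <- "group" %in% names(df) && !all(is.na(df$group))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x0, .data$y0,
                                        group = .data$root_id))
  if (color_ci) {
    df$ci_capped <- pmin(df$kappa_smooth, vmax)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x0, .data$y0,
                                          group = .data$root_id,
                                          colour = .data$ci_capped)) +
      ggplot2::geom_path(linewidth = 0.4) +
      ggplot2::scale_colour_viridis_c(name = expression(CI ~ (cm^-1)),
                                      limits = c(0, vmax))
  } else {
    p <- p + ggplot2::geom_path(linewidth = 0.3, alpha = 0.7)
  }
  if (has_group) p <- p + ggplot2::facet_wrap(~group)
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Circular histogram of root-tip angles
#'
#' Polar bar chart of tip-angle classes per group (counts in classes of
#' `class_width_deg`), with 0 at the horizontal and +90 pointing down the
#' page like a root growing with gravity.
#'
#' @param angles Tibble with `group` and `angle_deg` columns.
#' @param class_width_deg Class width, degrees (default 20).
#' @return A ggplot object.
#' @export
plot_angle_histogram <- function(angles, class_width_deg = 20) {
  b <- bin_angles(angles, class_width_deg = class_width_deg)
  h <- b$histogram
  h$mid <- (h$class_lo + h$class_hi) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = class_width_deg, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 150, by = 30)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "tip angle (deg)", y = "count") +
    ggplot2::theme_minimal()
}

#' Curvature versus distance from the base, with group smoothers
#'
#' @param profiles Per-point tibble (columns group, arc_pos, kappa_smooth,
#'   valid).
#' @param family,span Passed to [ci_distance_smoother()].
#' @return A ggplot object.
#' @export
plot_ci_distance <- function(profiles, family = "loess", span = 0.3) {
  sm <- ci_distance_smoother(profiles, family = family, span = span)
  dat <- profiles[profiles$valid, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(.data$arc_pos, .data$kappa_smooth)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.15) +
    ggplot2::geom_line(data = sm,
                       ggplot2::aes(.data$arc_pos, .data$kappa_fit),
                       colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "distance from basal point (cm)",
                  y = expression(CI ~ (cm^-1))) +
    ggplot2::theme_minimal()
}
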