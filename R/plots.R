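#' Plot 1-D spatial profiles with SEM ribbons
#'
#' Mean response per axis bin with a +/-1 SEM band, one colour per
#' condition; faceted by subject when a `subject` column is present.
#'
#' @param profile A `spatial_profile` (or several bound together).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profile) {
  check_columns(profile, c("bin_center", "mean_response", "sem", "condition"),
                "profile")
  p <- ggplot(profile, aes(x = .data$bin_center, y = .data$mean_response,
                           colour = .data$condition,
                           fill = .data$condition)) +
    ggplot2::geom_ribbon(
      aes(ymin = .data$mean_response - .data$sem,
          ymax = .data$mean_response + .data$sem),
      alpha = 0.25, colour = NA, na.rm = TRUE
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "position along axis (mm, posterior → anterior)",
      y = "response (a.u.)", colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
  if ("subject" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(~subject)
  }
  p
}

#' @export
autoplot.spatial_profile <- function(object, ...) plot_profiles(object)

#' Plot a voxel pattern on its patch
#'
#' Tile map of a pattern (e.g. an eyes-minus-mouth contrast) on the patch
#' grid, with the anatomical axis overlaid when given.
#'
#' @param pattern Data frame with `voxel`, `value`.
#' @param patch The `cortical_patch` giving voxel coordinates.
#' @param axis Optional `anatomical_axis` to overlay.
#' @return A ggplot object.
#' @export
plot_pattern <- function(pattern, patch, axis = NULL) {
  check_columns(pattern, c("voxel", "value"), "pattern")
  df <- left_join(pattern, patch, by = "voxel")
  p <- ggplot(df, aes(x = .data$x_mm, y = .data$y_mm, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "value") +
    ggplot2::theme_minimal()
  if (!is.null(axis)) {
    p <- p + ggplot2::geom_path(
      data = as_tibble(axis), aes(x = .data$x_mm, y = .data$y_mm),
      inherit.aes = FALSE, linewidth = 1
    )
  }
  p
}

#' Plot one aperture frame
#'
#' @param apertures An `aperture_stack`.
#' @param frame Frame index.
#' @return A ggplot object.
#' @export
plot_aperture_frame <- function(apertures, frame = 1) {
  stopifnot(inherits(apertures, "aperture_stack"))
  df <- tibble(x = apertures$x, y = apertures$y,
               on = apertures$frames[frame, ])
  ggplot(df, aes(x = .data$x, y = .data$y, fill = factor(.data$on))) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "grey20")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
}
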