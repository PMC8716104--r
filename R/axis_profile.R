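#' Project points onto an anatomical axis
#'
#' For each point, finds the closest location on the axis polyline (the
#' orthogonal foot within a segment, or a segment endpoint) and returns its
#' arc-length position along the axis together with the Euclidean distance to
#' it. Points projecting beyond either polyline end clamp to that end, so the
#' position always lies in `[0, total arc length]`. When two locations on the
#' polyline are exactly equidistant, the smaller arc-length position wins
#' (deterministic tie-break).
#'
#' The posterior end of the axis is position 0: smaller positions are more
#' posterior.
#'
#' @param coords Data frame with columns `x_mm`, `y_mm` (extra columns, e.g.
#'   `voxel`, are carried through). An empty frame returns an empty result.
#' @param axis An [anatomical_axis()].
#'
#' @return The input tibble with columns `position_mm` (arc length of the
#'   closest axis point) and `distance_mm` (distance to it) appended.
#' @examples
#' ax <- anatomical_axis(rbind(c(0, 0), c(10, 0)))
#' project_to_axis(data.frame(x_mm = 3, y_mm = 4), ax)
#' @export
project_to_axis <- function(coords, axis) {
  stopifnot(inherits(axis, "anatomical_axis"))
  coords <- as_tibble(coords)
  check_columns(coords, c("x_mm", "y_mm"), "coords")
  n <- nrow(coords)
  if (n == 0) {
    coords$position_mm <- numeric(0)
    coords$distance_mm <- numeric(0)
    return(coords)
  }
  px <- coords$x_mm
  py <- coords$y_mm
  best_d2 <- rep(Inf, n)
  best_pos <- rep(NA_real_, n)
  ax <- axis$x_mm
  ay <- axis$y_mm
  arc <- axis$arc_mm
  for (s in seq_len(length(ax) - 1)) {
    dx <- ax[s + 1] - ax[s]
    dy <- ay[s + 1] - ay[s]
    len2 <- dx^2 + dy^2
    tt <- pmin(1, pmax(0, ((px - ax[s]) * dx + (py - ay[s]) * dy) / len2))
    qx <- ax[s] + tt * dx
    qy <- ay[s] + tt * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    pos <- arc[s] + tt * sqrt(len2)
    better <- d2 < best_d2 - 1e-12 |
      (abs(d2 - best_d2) <= 1e-12 & pos < best_pos)
    best_d2[better] <- d2[better]
    best_pos[better] <- pos[better]
  }
  coords$position_mm <- best_pos
  coords$distance_mm <- sqrt(best_d2)
  coords
}

#' Bin responses along the axis into a 1-D spatial profile
#'
#' Groups projected positions into fixed-width bins starting at 0 and reports
#' the per-bin mean response and its standard error. Empty bins are omitted.
#' The default bin width of 1.2 mm is one voxel pitch.
#'
#' @param data Data frame with columns `position_mm` and `value` (and
#'   optionally `condition`, in which case profiles are computed per
#'   condition).
#' @param bin_width Bin width in mm (> 0). Default 1.2.
#'
#' @return A `spatial_profile`: a tibble with columns `condition` (if
#'   present), `bin_center` (mm), `mean_response`, `sem` (`NA` for
#'   single-point bins), and `n` (points per bin), ordered by bin.
#' @export
build_profile <- function(data, bin_width = 1.2) {
  check_number(bin_width, "bin_width", min = 0, strict = TRUE)
  data <- as_tibble(data)
  check_columns(data, c("position_mm", "value"), "data")
  if (!"condition" %in% names(data)) data$condition <- "value"
  data$.bin <- floor(data$position_mm / bin_width)
  out <- data |>
    group_by(.data$condition, .data$.bin) |>
    summarise(
      bin_center = (.bin[1] + 0.5) * bin_width,
      mean_response = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$condition, .data$.bin) |>
    select("condition", "bin_center", "mean_response", "sem", "n")
  structure(out, class = c("spatial_profile", class(out)),
            bin_width = bin_width)
}

#' Gradient correlation between a response contrast and axis position
#'
#' Pearson correlation between per-vertex contrast values (e.g. eyes minus
#' mouth) and their arc-length position along the posterior-anterior axis.
#' Because position 0 is posterior, a negative r means the first condition of
#' the contrast is posterior-biased. Computed at the vertex level by default;
#' `level = "bin"` first averages within [build_profile()] bins and
#' correlates bin means against bin centers.
#'
#' The statistic is invariant to sign-preserving affine rescaling of either
#' input, so upstream normalization conventions cannot change it.
#'
#' @param data Data frame with columns `position_mm` and `value` (the
#'   contrast), at least 3 rows, both columns non-constant.
#' @param level `"vertex"` (default) or `"bin"`.
#' @param bin_width Bin width in mm when `level = "bin"`.
#'
#' @return Pearson r (single number).
#' @export
gradient_correlation <- function(data, level = c("vertex", "bin"),
                                 bin_width = 1.2) {
  level <- match.arg(level)
  data <- as_tibble(data)
  check_columns(data, c("position_mm", "value"), "data")
  if (level == "bin") {
    prof <- build_profile(data, bin_width = bin_width)
    data <- tibble(position_mm = prof$bin_center, value = prof$mean_response)
  }
  if (nrow(data) < 3) {
    stop_facegrad("Gradient correlation needs at least 3 points.",
                  "facegrad_insufficient_data"
    )
  }
  if (stats::sd(data$position_mm) == 0 || stats::sd(data$value) == 0) {
    stop_facegrad("Gradient correlation is undefined for constant input.",
                  "facegrad_zero_variance")
  }
  cor(data$position_mm, data$value)
}
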