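#' Create a regular cortical patch
#'
#' Builds a regular grid of vertices standing in for a flattened patch of
#' cortical surface (2-D, the default) or a small volumetric slab (3-D when
#' `n_slices > 1`). Coordinates are in millimetres; the default spacing of
#' 1.2 mm matches a high-field acquisition with 1.2 mm isotropic voxels.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param spacing_mm Vertex spacing in mm (> 0). Default 1.2.
#' @param n_slices Number of slices in the third dimension (default 1:
#'   a flat patch).
#'
#' @return A `cortical_patch`: a tibble with columns `voxel` (unique id,
#'   `"v1"`, `"v2"`, ...), `row`, `col`, `slice`, `x_mm`, `y_mm`, `z_mm`.
#'   Grid connectivity (4-neighbour in 2-D, 6-neighbour in 3-D) is available
#'   via [patch_adjacency()].
#' @examples
#' make_patch(2, 3, spacing_mm = 1)
#' @export
make_patch <- function(n_rows, n_cols, spacing_mm = 1.2, n_slices = 1L) {
  check_number(n_rows, "n_rows", min = 1)
  check_number(n_cols, "n_cols", min = 1)
  check_number(n_slices, "n_slices", min = 1)
  check_number(spacing_mm, "spacing_mm", min = 0, strict = TRUE)
  grid <- expand.grid(
    row = seq_len(n_rows), col = seq_len(n_cols), slice = seq_len(n_slices),
    KEEP.OUT.ATTRS = FALSE
  )
  # order: column-major along x first so positions along the axis vary fastest
  grid <- grid[order(grid$slice, grid$row, grid$col), , drop = FALSE]
  out <- tibble(
    voxel = paste0("v", seq_len(nrow(grid))),
    row = grid$row, col = grid$col, slice = grid$slice,
    x_mm = (grid$col - 1) * spacing_mm,
    y_mm = (grid$row - 1) * spacing_mm,
    z_mm = (grid$slice - 1) * spacing_mm
  )
  structure(out, class = c("cortical_patch", class(out)),
            spacing_mm = spacing_mm,
            dims = c(n_rows, n_cols, n_slices))
}

#' Grid adjacency of a cortical patch
#'
#' Face-touching connectivity: 4-neighbour within a slice, plus across-slice
#' neighbours when the patch is volumetric (6-connectivity), the most
#' conservative standard choice for "continuous voxels".
#'
#' @param patch A `cortical_patch` from [make_patch()].
#' @return A named list mapping each voxel id to the character vector of its
#'   neighbours. The relation is symmetric.
#' @export
patch_adjacency <- function(patch) {
  check_columns(patch, c("voxel", "row", "col", "slice"), "patch")
  key <- function(r, c, s) paste(r, c, s, sep = "_")
  idx <- stats::setNames(patch$voxel, key(patch$row, patch$col, patch$slice))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  adj <- lapply(seq_len(nrow(patch)), function(i) {
    nb <- key(patch$row[i] + offs[, 1], patch$col[i] + offs[, 2],
              patch$slice[i] + offs[, 3])
    unname(idx[nb[nb %in% names(idx)]])
  })
  stats::setNames(adj, patch$voxel)
}

#' Define an anatomical axis polyline
#'
#' An ordered polyline in the patch coordinate frame representing the
#' anatomical direction (e.g. the mid-fusiform or occipitotemporal sulcus)
#' along which 1-D response profiles are built. The first point is the
#' posterior end: arc-length position 0. Positions increase toward the
#' anterior end, so "more posterior" always means "smaller position".
#'
#' @param points A two-column numeric matrix or data frame of (x, y)
#'   coordinates in mm, ordered posterior to anterior, with at least two
#'   points and no repeated consecutive point.
#'
#' @return An `anatomical_axis`: a tibble with columns `x_mm`, `y_mm`, and
#'   `arc_mm` (cumulative arc length, strictly increasing from 0).
#' @examples
#' anatomical_axis(rbind(c(0, 0), c(10, 0)))
#' @export
anatomical_axis <- function(points) {
  pts <- as.matrix(as.data.frame(points))
  if (ncol(pts) < 2 || nrow(pts) < 2) {
    stop_facegrad("An axis needs at least two 2-D points.",
                  "facegrad_invalid_argument")
  }
  pts <- pts[, 1:2, drop = FALSE]
  if (!all(is.finite(pts))) {
    stop_facegrad("Axis coordinates must be finite.",
                  "facegrad_invalid_argument")
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg <= 0)) {
    stop_facegrad("Consecutive axis points must be distinct.",
                  "facegrad_invalid_argument")
  }
  out <- tibble(x_mm = pts[, 1], y_mm = pts[, 2], arc_mm = c(0, cumsum(seg)))
  structure(out, class = c("anatomical_axis", class(out)))
}

#' Gaussian spatial smoothing on a patch
#'
#' Smooths per-voxel values with a 2-D (or 3-D) Gaussian kernel over the
#' patch coordinates, the standard preprocessing step for localizer maps
#' (main-experiment patterns are left unsmoothed to preserve fine-scale
#' structure). Weights are normalized per voxel, so constant maps are
#' preserved exactly.
#'
#' @param patch A `cortical_patch`.
#' @param values Numeric vector, one value per patch voxel (patch order).
#' @param fwhm_mm Kernel full width at half maximum in mm (default 2).
#' @return Smoothed numeric vector, same length and order.
#' @export
smooth_patch_values <- function(patch, values, fwhm_mm = 2) {
  check_number(fwhm_mm, "fwhm_mm", min = 0, strict = TRUE)
  if (length(values) != nrow(patch)) {
    stop_facegrad("`values` must have one entry per patch voxel.",
                  "facegrad_invalid_argument")
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  xyz <- cbind(patch$x_mm, patch$y_mm, patch$z_mm)
  d2 <- as.matrix(stats::dist(xyz))^2
  W <- exp(-d2 / (2 * sigma^2))
  W[d2 > (3 * sigma)^2] <- 0 # compact support at 3 sigma
  unname(as.vector(W %*% values) / rowSums(W))
}
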