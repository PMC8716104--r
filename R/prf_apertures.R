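#' Aperture stacks for retinotopic mapping stimuli
#'
#' Binary stimulus apertures sampled once per TR on a square pixel grid
#' covering the stimulated field (default 64 x 64 pixels over +/-10 degrees
#' of visual angle). Wedge stacks rotate a 45 degree wedge once per cycle;
#' ring stacks sweep an annulus across eccentricity with a rest period
#' closing each cycle. Blank (fixation) frames can pad the start and end of
#' a run.
#'
#' @param span_deg Angular span of the wedge in degrees, in (0, 360).
#' @param period_s Rotation period in seconds; must be a multiple of `tr`.
#' @param direction `"ccw"` or `"cw"` for wedges; `"expand"` or
#'   `"contract"` for rings.
#' @param radius_deg Radius of the stimulated field in degrees (default 10).
#' @param tr Sampling interval (repetition time) in seconds (default 2).
#' @param n_cycles Number of stimulus cycles (default 8).
#' @param grid_n Pixels per side of the square grid (default 64).
#' @param blank_s Blank fixation time prepended and appended, in seconds
#'   (default 22); must be a multiple of `tr`.
#'
#' @return An `aperture_stack`: list with `frames` (time x pixel 0/1
#'   matrix), `x`, `y` (pixel-centre coordinates in degrees, length
#'   `grid_n^2`), `tr`, `radius_deg`, `grid_n`.
#' @name apertures
NULL

new_aperture_stack <- function(frames, x, y, tr, radius_deg, grid_n) {
  structure(list(frames = frames, x = x, y = y, tr = tr,
                 radius_deg = radius_deg, grid_n = grid_n),
            class = "aperture_stack")
}

#' @export
print.aperture_stack <- function(x, ...) {
  cat(sprintf(
    "<aperture_stack> %d frames x %d pixels (%dx%d grid, +/-%g deg, TR %g s)\n",
    nrow(x$frames), ncol(x$frames), x$grid_n, x$grid_n, x$radius_deg, x$tr))
  invisible(x)
}

pixel_grid <- function(grid_n, radius_deg) {
  # pixel centres of a grid_n x grid_n grid spanning [-radius, radius]
  half <- radius_deg
  centers <- seq(-half, half, length.out = grid_n + 1)
  centers <- (centers[-1] + centers[-(grid_n + 1)]) / 2
  g <- expand.grid(x = centers, y = centers, KEEP.OUT.ATTRS = FALSE)
  list(x = g$x, y = g$y)
}

check_multiple <- function(value, tr, name) {
  if (abs(value / tr - round(value / tr)) > 1e-9) {
    stop_facegrad(sprintf("`%s` (%g s) must be a multiple of TR (%g s).",
                          name, value, tr),
                  "facegrad_invalid_argument")
  }
}

#' @rdname apertures
#' @export
make_wedge_apertures <- function(span_deg = 45, period_s = 32,
                                 direction = c("ccw", "cw"),
                                 radius_deg = 10, tr = 2, n_cycles = 8,
                                 grid_n = 64, blank_s = 22) {
  direction <- match.arg(direction)
  check_number(span_deg, "span_deg", min = 0, strict = TRUE)
  if (span_deg >= 360) {
    stop_facegrad("`span_deg` must be < 360.", "facegrad_invalid_argument")
  }
  check_multiple(period_s, tr, "period_s")
  check_multiple(blank_s, tr, "blank_s")
  grid <- pixel_grid(grid_n, radius_deg)
  in_disk <- grid$x^2 + grid$y^2 <= radius_deg^2
  # work in degrees: wedge boundaries land on exactly representable values,
  # so frames are bit-identical across cycles and between cw/ccw reversals
  theta <- (atan2(grid$y, grid$x) * 180 / pi) %% 360

  per_cycle <- as.integer(round(period_s / tr))
  n_frames <- per_cycle * n_cycles
  sgn <- if (direction == "ccw") 1 else -1
  frames <- matrix(0, nrow = n_frames, ncol = grid_n^2)
  for (k in seq_len(n_frames)) {
    j <- (k - 1) %% per_cycle
    start <- (sgn * 360 * j / per_cycle) %% 360
    rel <- (theta - start) %% 360
    frames[k, ] <- as.numeric(in_disk & rel < span_deg)
  }
  frames <- pad_blanks(frames, blank_s, tr, grid_n^2)
  new_aperture_stack(frames, grid$x, grid$y, tr, radius_deg, grid_n)
}

#' @rdname apertures
#' @param sweep_s Ring sweep duration per cycle in seconds (default 28).
#' @param rest_s Rest after each sweep in seconds (default 4).
#' @param ring_width_deg Annulus thickness in degrees (default
#'   `radius_deg / 5`).
#' @export
make_ring_apertures <- function(sweep_s = 28, rest_s = 4,
                                direction = c("expand", "contract"),
                                radius_deg = 10, tr = 2, n_cycles = 8,
                                grid_n = 64, blank_s = 22,
                                ring_width_deg = radius_deg / 5) {
  direction <- match.arg(direction)
  check_multiple(sweep_s, tr, "sweep_s")
  check_multiple(rest_s, tr, "rest_s")
  grid <- pixel_grid(grid_n, radius_deg)
  ecc <- sqrt(grid$x^2 + grid$y^2)

  n_sweep <- as.integer(round(sweep_s / tr))
  n_rest <- as.integer(round(rest_s / tr))
  # outer edge ramps from one ring width to the field edge across the sweep
  outer <- ring_width_deg +
    (radius_deg - ring_width_deg) * (seq_len(n_sweep) - 1) / (n_sweep - 1)
  if (direction == "contract") outer <- rev(outer)
  cycle <- matrix(0, nrow = n_sweep + n_rest, ncol = grid_n^2)
  for (k in seq_len(n_sweep)) {
    cycle[k, ] <- as.numeric(ecc <= outer[k] & ecc > outer[k] - ring_width_deg)
  }
  frames <- do.call(rbind, rep(list(cycle), n_cycles))
  frames <- pad_blanks(frames, blank_s, tr, grid_n^2)
  new_aperture_stack(frames, grid$x, grid$y, tr, radius_deg, grid_n)
}

pad_blanks <- function(frames, blank_s, tr, n_pix) {
  n_blank <- as.integer(round(blank_s / tr))
  if (n_blank == 0) return(frames)
  blank <- matrix(0, nrow = n_blank, ncol = n_pix)
  rbind(blank, frames, blank)
}

#' Concatenate aperture stacks in time
#'
#' Joins several runs' apertures (same grid and TR) into one stack, as used
#' when fitting the pRF model to all run types jointly.
#'
#' @param ... `aperture_stack` objects on identical grids.
#' @return A single `aperture_stack`.
#' @export
concat_apertures <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1 && is.list(stacks[[1]]) &&
      !inherits(stacks[[1]], "aperture_stack")) {
    stacks <- stacks[[1]]
  }
  stopifnot(length(stacks) >= 1)
  base <- stacks[[1]]
  for (s in stacks[-1]) {
    stopifnot(identical(s$grid_n, base$grid_n), identical(s$tr, base$tr),
              identical(s$radius_deg, base$radius_deg))
  }
  frames <- do.call(rbind, lapply(stacks, `[[`, "frames"))
  new_aperture_stack(frames, base$x, base$y, base$tr, base$radius_deg,
                     base$grid_n)
}
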