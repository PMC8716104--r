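#' Normalize a response pattern across voxels
#'
#' Z-scores a condition's spatial response pattern (mean 0, SD 1 across
#' voxels, SD with the n-1 convention) to remove overall amplitude
#' differences between conditions before patterns are contrasted.
#' Mean-division (`method = "mean"`) is offered as an alternative;
#' downstream gradient correlations are invariant to the choice because
#' both are sign-preserving affine maps of the pattern.
#'
#' @param pattern Data frame with columns `voxel`, `value`; at least 3
#'   voxels with nonzero variance.
#' @param method `"zscore"` (default) or `"mean"` (divide by the mean;
#'   requires a nonzero mean).
#'
#' @return The pattern tibble with `value` normalized and attribute
#'   `normalized = method`.
#' @export
normalize_pattern <- function(pattern, method = c("zscore", "mean")) {
  method <- match.arg(method)
  pattern <- as_tibble(pattern)
  check_columns(pattern, c("voxel", "value"), "pattern")
  if (nrow(pattern) < 3) {
    stop_facegrad("Pattern normalization needs at least 3 voxels.",
                  "facegrad_insufficient_data")
  }
  if (any(!is.finite(pattern$value))) {
    stop_facegrad("Pattern values must be finite.", "facegrad_invalid_argument")
  }
  if (method == "zscore") {
    s <- stats::sd(pattern$value)
    if (s == 0) {
      stop_facegrad("Cannot z-score a constant pattern.",
                    "facegrad_zero_variance")
    }
    pattern$value <- (pattern$value - mean(pattern$value)) / s
  } else {
    m <- mean(pattern$value)
    if (m == 0) {
      stop_facegrad("Cannot mean-normalize a zero-mean pattern.",
                    "facegrad_zero_variance")
    }
    pattern$value <- pattern$value / m
  }
  attr(pattern, "normalized") <- method
  pattern
}

#' Contrast two normalized patterns
#'
#' Voxelwise difference `a - b` of two response patterns defined on the same
#' voxel set, e.g. the eyes-minus-mouth contrast whose spatial layout the
#' axis-profile analysis quantifies. Both patterns should be normalized
#' first so the contrast reflects spatial bias, not amplitude.
#'
#' @param a,b Patterns (data frames with `voxel`, `value`) on identical
#'   voxel sets.
#'
#' @return A pattern tibble (`voxel`, `value`) with attribute
#'   `condition = "a_minus_b"` style label built from the inputs' `condition`
#'   attributes when available.
#' @export
contrast_map <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  check_columns(a, c("voxel", "value"), "a")
  check_columns(b, c("voxel", "value"), "b")
  if (!identical(sort(a$voxel), sort(b$voxel))) {
    stop_facegrad("Patterns are defined on different voxel sets.",
                  "facegrad_alignment_error")
  }
  bv <- b$value[match(a$voxel, b$voxel)]
  out <- tibble(voxel = a$voxel, value = a$value - bv)
  lab_a <- attr(a, "condition") %||% "a"
  lab_b <- attr(b, "condition") %||% "b"
  attr(out, "condition") <- paste0(lab_a, "_minus_", lab_b)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Regress a shared general pattern out of a part pattern
#'
#' Simple OLS of the face-part pattern on the general pattern (one regressor
#' plus intercept, across voxels). The residuals are the part-specific
#' pattern with the shared component — intrinsic BOLD sensitivity, vein
#' distribution, and any other factor common to all conditions — removed.
#' R-squared reports the fraction of part-pattern variance the general
#' pattern explains.
#'
#' @param part Data frame (`voxel`, `value`): the face-part pattern.
#' @param general Data frame (`voxel`, `value`): the shared pattern (e.g.
#'   the whole-face or everyday-object response); must be non-constant and
#'   cover the same voxel set.
#'
#' @return A `pattern_regression` object: list with `residuals` (pattern
#'   tibble `voxel`, `value`), `r_squared` (fraction in `[0, 1]`), `slope`,
#'   `intercept`, and `n_voxels`. [tidy()] returns the residuals; [glance()]
#'   the fit summary.
#' @export
regress_out <- function(part, general) {
  part <- as_tibble(part); general <- as_tibble(general)
  check_columns(part, c("voxel", "value"), "part")
  check_columns(general, c("voxel", "value"), "general")
  if (!identical(sort(part$voxel), sort(general$voxel))) {
    stop_facegrad("Patterns are defined on different voxel sets.",
                  "facegrad_alignment_error")
  }
  g <- general$value[match(part$voxel, general$voxel)]
  y <- part$value
  if (stats::sd(g) == 0) {
    stop_facegrad("The general pattern is constant; regression is undefined.",
                  "facegrad_zero_variance")
  }
  slope <- stats::cov(g, y) / stats::var(g)
  intercept <- mean(y) - slope * mean(g)
  fitted <- intercept + slope * g
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
  structure(
    list(
      residuals = tibble(voxel = part$voxel, value = res),
      r_squared = r2, slope = slope, intercept = intercept,
      n_voxels = length(y)
    ),
    class = "pattern_regression"
  )
}

#' @export
print.pattern_regression <- function(x, ...) {
  cat(sprintf(
    "<pattern_regression> %d voxels, slope %.4g, intercept %.4g, R^2 = %.3f\n",
    x$n_voxels, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @rdname regress_out
#' @param x A `pattern_regression`.
#' @param ... Unused.
#' @export
tidy.pattern_regression <- function(x, ...) x$residuals

#' @rdname regress_out
#' @export
glance.pattern_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, n_voxels = x$n_voxels)
}
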