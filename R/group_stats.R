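#' Group-level one-sample t test on per-subject correlations
#'
#' Tests whether per-subject gradient correlations differ from zero: a
#' one-sample t test on the raw r values with a two-sided p and Cohen's
#' d = mean(r) / sd(r). Raw r (not Fisher-z) is the default because the
#' conventional effect-size report d = mean/sd refers to the raw values; a
#' Fisher-z option is provided and flips nothing qualitatively for |r| well
#' below 1.
#'
#' @param rs Numeric vector of per-subject correlations, length >= 2 with
#'   nonzero variance.
#' @param transform `"raw"` (default) or `"fisher"` (atanh before testing;
#'   d is then on the z scale).
#'
#' @return A `gradient_stats` object: list with `per_subject_r`, `t`, `df`,
#'   `p` (two-sided), `cohens_d`, `mean_r`, `transform`. [tidy()] /
#'   [glance()] return a one-row tibble.
#' @examples
#' group_onesample_t(c(-0.6, -0.5, -0.7, -0.4, -0.55, -0.65))
#' @export
group_onesample_t <- function(rs, transform = c("raw", "fisher")) {
  transform <- match.arg(transform)
  if (length(rs) < 2 || anyNA(rs)) {
    stop_facegrad("Need >= 2 complete per-subject values.",
                  "facegrad_insufficient_data")
  }
  x <- if (transform == "fisher") atanh(rs) else rs
  if (stats::sd(x) == 0) {
    stop_facegrad("Per-subject values have zero variance.",
                  "facegrad_zero_variance")
  }
  tt <- t.test(x, mu = 0)
  structure(
    list(
      per_subject_r = rs,
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p = tt$p.value,
      cohens_d = mean(x) / stats::sd(x),
      mean_r = mean(rs),
      transform = transform
    ),
    class = "gradient_stats"
  )
}

#' @export
print.gradient_stats <- function(x, ...) {
  cat(sprintf(
    "<gradient_stats> n = %d, mean r = %.3f, t(%d) = %.2f, p = %.4g, Cohen's d = %.2f\n",
    length(x$per_subject_r), x$mean_r, x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' @rdname group_onesample_t
#' @param x A `gradient_stats` object.
#' @param ... Unused.
#' @export
tidy.gradient_stats <- function(x, ...) {
  tibble(n = length(x$per_subject_r), mean_r = x$mean_r, t = x$t,
         df = x$df, p = x$p, cohens_d = x$cohens_d)
}

#' @rdname group_onesample_t
#' @export
glance.gradient_stats <- function(x, ...) tidy(x)

#' Paired t test between two conditions' amplitudes
#'
#' Paired (within-subject) two-sided t test comparing mean response
#' amplitudes between two conditions across subjects, as used to compare
#' e.g. eyes vs nose response amplitudes within an ROI.
#'
#' @param amplitudes Data frame with columns `subject`, `condition`,
#'   `amplitude`; every subject must have both conditions (complete pairs).
#' @param a,b Condition names.
#'
#' @return One-row tibble `t`, `df`, `p`, `mean_diff`, `n`. Identical
#'   columns give `t = 0`, `p = 1`; a constant nonzero difference (zero
#'   variance) is a degenerate-input error.
#' @export
paired_condition_t <- function(amplitudes, a, b) {
  check_columns(amplitudes, c("subject", "condition", "amplitude"),
                "amplitudes")
  wide <- amplitudes |>
    filter(.data$condition %in% c(a, b)) |>
    tidyr::pivot_wider(id_cols = "subject",
                       names_from = "condition", values_from = "amplitude")
  if (!all(c(a, b) %in% names(wide)) || anyNA(wide[[a]]) || anyNA(wide[[b]])) {
    stop_facegrad("Every subject needs an amplitude for both conditions.",
                  "facegrad_incomplete_data")
  }
  if (nrow(wide) < 2) {
    stop_facegrad("Paired t needs >= 2 subjects.",
                  "facegrad_insufficient_data")
  }
  d <- wide[[a]] - wide[[b]]
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) { # zero up to rounding
    if (all(d == 0)) {
      return(tibble(t = 0, df = length(d) - 1L, p = 1,
                    mean_diff = 0, n = length(d)))
    }
    stop_facegrad("Differences have zero variance; paired t is undefined.",
                  "facegrad_zero_variance")
  }
  tt <- t.test(wide[[a]], wide[[b]], paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = mean(d), n = length(d))
}

#' Odd/even split-half reliability of a voxelwise contrast
#'
#' Splits the runs into odd and even halves, averages the per-voxel beta
#' difference `cond_a - cond_b` within each half, and correlates the two
#' half-estimates across voxels. A high r means the voxelwise contrast
#' (e.g. the eyes-mouth bias map) is stable within subject.
#'
#' @param betas_by_run Long data frame `voxel`, `run`, `condition`, `beta`;
#'   `run` must be integer-like so odd/even is defined. At least 2 runs and
#'   3 shared voxels.
#' @param cond_a,cond_b Condition names for the contrast.
#'
#' @return Pearson r between the odd-half and even-half bias maps.
#' @export
split_half_reliability <- function(betas_by_run, cond_a, cond_b) {
  check_columns(betas_by_run, c("voxel", "run", "condition", "beta"),
                "betas_by_run")
  runs <- sort(unique(betas_by_run$run))
  if (length(runs) < 2) {
    stop_facegrad("Split-half reliability needs >= 2 runs.",
                  "facegrad_insufficient_data")
  }
  wide <- betas_by_run |>
    filter(.data$condition %in% c(cond_a, cond_b)) |>
    tidyr::pivot_wider(id_cols = c("voxel", "run"),
                       names_from = "condition", values_from = "beta")
  if (!all(c(cond_a, cond_b) %in% names(wide)) ||
      anyNA(wide[[cond_a]]) || anyNA(wide[[cond_b]])) {
    stop_facegrad("Both conditions must be present in every run.",
                  "facegrad_incomplete_data")
  }
  wide$diff <- wide[[cond_a]] - wide[[cond_b]]
  wide$half <- ifelse(as.integer(wide$run) %% 2 == 1, "odd", "even")
  halves <- wide |>
    group_by(.data$voxel, .data$half) |>
    summarise(bias = mean(.data$diff), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "bias")
  if (!all(c("odd", "even") %in% names(halves))) {
    stop_facegrad("Need at least one odd and one even run.",
                  "facegrad_insufficient_data")
  }
  if (nrow(halves) < 3) {
    stop_facegrad("Split-half reliability needs >= 3 shared voxels.",
                  "facegrad_insufficient_data")
  }
  if (stats::sd(halves$odd) == 0 || stats::sd(halves$even) == 0) {
    stop_facegrad("A half has constant bias; correlation is undefined.",
                  "facegrad_zero_variance")
  }
  cor(halves$odd, halves$even)
}

#' Bonferroni-adjust a vector of p values
#'
#' Thin convenience wrapper around [stats::p.adjust()]; not applied by any
#' pipeline default, since per-ROI tests are conventionally reported
#' uncorrected.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
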