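#' Ground truth for a simulated patch
#'
#' Describes the planted structure of a synthetic experiment: a shared
#' baseline response pattern (the "general" intrinsic BOLD sensitivity
#' profile common to all conditions), one linear response gradient per
#' condition along the anatomical axis, i.i.d. Gaussian noise, and an
#' optional set of vein-contaminated voxels whose face response is inflated
#' above the percent-signal-change exclusion threshold.
#'
#' @param patch A `cortical_patch`.
#' @param axis An `anatomical_axis`; used to assign each voxel its axis
#'   position for the gradients.
#' @param slopes Named numeric vector: condition -> gradient slope in
#'   response units (percent signal change) per mm of axis position.
#'   Conditions absent from `slopes` get slope 0.
#' @param baseline Per-voxel baseline pattern: either a single number
#'   (constant), a numeric vector of length `nrow(patch)`, or `NULL`
#'   (default) for a smooth deterministic bump pattern that mimics a shared
#'   sensitivity profile.
#' @param baseline_mean Mean response level (PSC units) added to every
#'   condition on top of the gradient; default 1.
#' @param condition_means Optional named numeric vector of per-condition
#'   mean response levels (PSC units) overriding `baseline_mean`, used to
#'   plant amplitude differences (e.g. faces > objects for the localizer
#'   contrast). Conditions not named fall back to `baseline_mean`.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian beta noise
#'   (>= 0).
#' @param vein_ids Character vector of voxel ids (subset of
#'   `patch$voxel`) to contaminate; default none.
#' @param vein_psc Face-condition percent signal change planted in vein
#'   voxels; must exceed the 4% exclusion threshold (default 6).
#' @param ar1 AR(1) coefficient for temporally correlated scan noise in
#'   [simulate_timeseries()]; default 0 (white noise).
#'
#' @return A `ground_truth` list used by [simulate_betas()].
#' @export
ground_truth <- function(patch, axis, slopes, baseline = NULL,
                         baseline_mean = 1, condition_means = NULL,
                         noise_sd = 0,
                         vein_ids = character(), vein_psc = 6, ar1 = 0) {
  stopifnot(inherits(patch, "cortical_patch"), inherits(axis, "anatomical_axis"))
  check_number(noise_sd, "noise_sd", min = 0)
  if (is.null(names(slopes)) || any(!nzchar(names(slopes)))) {
    stop_facegrad("`slopes` must be a named numeric vector (condition -> slope).",
                  "facegrad_invalid_argument")
  }
  if (any(!is.finite(slopes))) {
    stop_facegrad("Slopes must be finite.", "facegrad_invalid_argument")
  }
  if (length(vein_ids) > 0 && !all(vein_ids %in% patch$voxel)) {
    stop_facegrad("`vein_ids` must be a subset of patch voxels.",
                  "facegrad_invalid_argument")
  }
  n <- nrow(patch)
  if (is.null(baseline)) {
    # smooth deterministic bump: shared sensitivity profile across conditions
    cx <- mean(range(patch$x_mm)); cy <- mean(range(patch$y_mm))
    w <- max(diff(range(patch$x_mm)), diff(range(patch$y_mm)), 1)
    baseline <- 0.6 * exp(-((patch$x_mm - cx)^2 + (patch$y_mm - cy)^2) /
                            (2 * (w / 3)^2))
  } else if (length(baseline) == 1) {
    baseline <- rep(baseline, n)
  }
  if (length(baseline) != n || any(!is.finite(baseline))) {
    stop_facegrad("`baseline` must be finite, length 1 or one per voxel.",
                  "facegrad_invalid_argument")
  }
  structure(
    list(patch = patch, axis = axis, slopes = slopes, baseline = baseline,
         baseline_mean = baseline_mean, condition_means = condition_means,
         noise_sd = noise_sd,
         vein_ids = vein_ids, vein_psc = vein_psc, ar1 = ar1),
    class = "ground_truth"
  )
}

#' Simulate per-voxel condition betas with a planted gradient
#'
#' Generates one beta per voxel and condition following
#' `beta_c(v) = baseline(v) + mean_c + slope_c * (position(v) - mean position)
#' + noise`, where `position(v)` is the voxel's arc-length position along
#' the anatomical axis and the noise is i.i.d. Gaussian with SD
#' `truth$noise_sd`. The gradient is applied to the centred position so that
#' `mean_c` stays the condition's mean amplitude over the patch; gradient
#' correlations are invariant to this centring. Vein voxels additionally have the face condition (and
#' only it) raised to `truth$vein_psc` so they exceed the standard 4% PSC
#' exclusion threshold by construction.
#'
#' Betas are in percent-signal-change units: when paired with
#' [simulate_timeseries()] (baseline signal 100), the GLM's
#' `100 * beta / baseline` recovers them directly.
#'
#' @param truth A [ground_truth()] object.
#' @param conditions Character vector of condition names to simulate.
#'   Conditions without an entry in `truth$slopes` get slope 0; a `slopes`
#'   entry naming a condition that is not simulated is an error (it almost
#'   certainly indicates a typo in the slope map).
#' @param seed Integer seed; identical `(truth, conditions, seed)` give
#'   bit-identical output.
#' @param face_condition Name of the condition the vein contamination
#'   applies to (default `"face"`).
#'
#' @return A `betamap` tibble (`voxel`, `condition`, `beta`, `baseline`,
#'   `psc`) with attributes `position` (named numeric, per-voxel axis
#'   position) and `truth`.
#' @export
simulate_betas <- function(truth, conditions, seed = 1L,
                           face_condition = "face") {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(conditions) == 0) {
    stop_facegrad("`conditions` must be non-empty.", "facegrad_invalid_argument")
  }
  unknown <- setdiff(names(truth$slopes), conditions)
  if (length(unknown) > 0) {
    stop_facegrad(
      sprintf("Slope map names condition(s) not being simulated: %s.",
              paste(unknown, collapse = ", ")),
      "facegrad_invalid_argument"
    )
  }
  patch <- truth$patch
  proj <- project_to_axis(patch, truth$axis)
  pos <- stats::setNames(proj$position_mm, patch$voxel)

  set.seed(as.integer(seed))
  n <- nrow(patch)
  pos_c <- unname(pos - mean(pos))
  rows <- lapply(conditions, function(cond) {
    slope <- if (cond %in% names(truth$slopes)) truth$slopes[[cond]] else 0
    level <- if (!is.null(truth$condition_means) &&
                 cond %in% names(truth$condition_means)) {
      truth$condition_means[[cond]]
    } else {
      truth$baseline_mean
    }
    beta <- unname(truth$baseline) + level + slope * pos_c +
      rnorm(n, 0, truth$noise_sd)
    tibble(voxel = patch$voxel, condition = cond, beta = beta)
  })
  out <- bind_rows(rows)
  if (length(truth$vein_ids) > 0 && face_condition %in% conditions) {
    vein <- out$condition == face_condition & out$voxel %in% truth$vein_ids
    out$beta[vein] <- truth$vein_psc + abs(out$beta[vein])
  }
  out$baseline <- 100
  out$psc <- out$beta # baseline signal 100 => beta in PSC units
  out <- new_betamap(out)
  attr(out, "position") <- pos
  attr(out, "truth") <- truth
  out
}

#' Simulate block-design BOLD time series from betas
#'
#' Forward model of the GLM: `y(v) = X beta(v) + noise`, with the design's
#' baseline column carrying a mean signal of 100 so that betas expressed in
#' percent signal change round-trip through [fit_glm()]. Noise is i.i.d.
#' Gaussian per scan by default; an AR(1) option generates temporally
#' correlated noise with the same marginal SD.
#'
#' @param design A `design_matrix` from [build_design()].
#' @param betas A `betamap` (long tibble `voxel`, `condition`, `beta`). Its
#'   condition set must match the design's conditions exactly.
#' @param noise_sd Scan noise SD (>= 0), in raw signal units (= PSC units
#'   here, since baseline is 100).
#' @param seed Integer seed.
#' @param ar1 AR(1) coefficient in [0, 1); default 0.
#' @param baseline_signal Mean signal level (default 100).
#'
#' @return Numeric matrix `n_scans` x `n_voxels` with voxel ids as column
#'   names.
#' @export
simulate_timeseries <- function(design, betas, noise_sd = 0, seed = 1L,
                                ar1 = 0, baseline_signal = 100) {
  stopifnot(inherits(design, "design_matrix"))
  check_columns(betas, c("voxel", "condition", "beta"), "betas")
  check_number(noise_sd, "noise_sd", min = 0)
  conds <- design$conditions
  have <- unique(betas$condition)
  if (!setequal(conds, have)) {
    stop_facegrad(
      sprintf("Condition mismatch: design has {%s}, betas have {%s}.",
              paste(conds, collapse = ", "), paste(have, collapse = ", ")),
      "facegrad_invalid_argument"
    )
  }
  B <- tidyr::pivot_wider(betas[, c("voxel", "condition", "beta")],
                          names_from = "condition", values_from = "beta")
  voxels <- B$voxel
  Bm <- t(as.matrix(B[, conds, drop = FALSE])) # conditions x voxels
  X <- design$matrix[, conds, drop = FALSE]
  signal <- X %*% Bm + baseline_signal
  set.seed(as.integer(seed))
  n_scans <- design$n_scans
  eps <- matrix(rnorm(n_scans * length(voxels), 0, noise_sd),
                nrow = n_scans)
  if (ar1 > 0) {
    # AR(1) with stationary marginal SD = noise_sd
    innov_sd <- sqrt(1 - ar1^2)
    for (k in 2:n_scans) {
      eps[k, ] <- ar1 * eps[k - 1, ] + innov_sd * eps[k, ] # eps rows are N(0, noise_sd)
    }
  }
  Y <- signal + eps
  colnames(Y) <- voxels
  Y
}

#' Simulate one synthetic subject end to end
#'
#' Convenience wrapper producing everything the pipeline needs for one
#' subject of the emulated main experiment: per-run block-design time series
#' for the planted betas, the design matrices, and the ground truth. Runs
#' use the standard layout (16 s blocks, two per condition, 16 s fixation at
#' start/middle/end, TR 2 s).
#'
#' @param truth A [ground_truth()] object.
#' @param conditions Conditions to simulate.
#' @param n_runs Number of runs (default 8).
#' @param scan_noise_sd Scan noise SD in signal units.
#' @param tr Repetition time in s (default 2).
#' @param seed Integer seed; run r uses `seed + r`.
#'
#' @return A list with elements `runs` (list of `n_scans` x `n_voxels`
#'   matrices), `designs` (list of design matrices), `betas` (the planted
#'   `betamap`), and `position` (per-voxel axis position).
#' @export
simulate_subject <- function(truth, conditions, n_runs = 8,
                             scan_noise_sd = 1, tr = 2, seed = 1L) {
  betas <- simulate_betas(truth, conditions, seed = seed)
  designs <- lapply(seq_len(n_runs), function(r) {
    blocks <- standard_run_blocks(conditions, run = r)
    build_design(blocks, tr = tr, n_scans = run_n_scans(blocks, tr = tr),
                 hrf = hrf_params())
  })
  runs <- lapply(seq_len(n_runs), function(r) {
    simulate_timeseries(designs[[r]], betas, noise_sd = scan_noise_sd,
                        seed = as.integer(seed) + r, ar1 = truth$ar1)
  })
  list(runs = runs, designs = designs, betas = betas,
       position = attr(betas, "position"))
}
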