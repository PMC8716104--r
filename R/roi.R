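#' Voxelwise localizer contrast across runs
#'
#' For each voxel, a paired t test across runs of the beta difference
#' between two conditions (e.g. faces vs objects), with a one-sided
#' uncorrected p value for `cond_a > cond_b` — the conventional statistic
#' for defining category-selective regions from localizer runs.
#'
#' Voxels whose run-to-run difference has zero variance are degenerate:
#' if the difference is identically zero the identity convention `t = 0`,
#' `p = 0.5` applies; otherwise t is undefined and the voxel is flagged
#' (`t = NA`, `degenerate = TRUE`) so it can never pass a threshold.
#'
#' @param betas_by_run Long data frame with columns `voxel`, `run`,
#'   `condition`, `beta`; at least 2 runs, complete for both conditions.
#' @param cond_a,cond_b Condition names; the contrast is `cond_a - cond_b`.
#'
#' @return A tibble with columns `voxel`, `t`, `df`, `p` (one-sided),
#'   `mean_diff`, `degenerate`.
#' @export
localizer_contrast <- function(betas_by_run, cond_a, cond_b) {
  check_columns(betas_by_run, c("voxel", "run", "condition", "beta"),
                "betas_by_run")
  n_runs <- length(unique(betas_by_run$run))
  if (n_runs < 2) {
    stop_facegrad("Localizer contrast needs at least 2 runs.",
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
  out <- wide |>
    group_by(.data$voxel) |>
    summarise(
      mean_diff = mean(.data$diff),
      sd_diff = stats::sd(.data$diff),
      n = dplyr::n(),
      .groups = "drop"
    )
  out$df <- out$n - 1L
  zero_var <- out$sd_diff == 0
  out$t <- ifelse(zero_var & out$mean_diff == 0, 0,
                  out$mean_diff / (out$sd_diff / sqrt(out$n)))
  out$t[zero_var & out$mean_diff != 0] <- NA_real_
  out$p <- pt(out$t, out$df, lower.tail = FALSE)
  out$degenerate <- zero_var & out$mean_diff != 0
  out[, c("voxel", "t", "df", "p", "mean_diff", "degenerate")]
}

#' Define an ROI from a thresholded statistical map
#'
#' Thresholds the localizer map at `p < p_threshold` (uncorrected) within an
#' anatomical search zone, extracts connected components on the patch grid
#' (4-connectivity in 2-D, 6-connectivity in 3-D), and returns the largest
#' component — the standard "largest cluster of continuous suprathreshold
#' voxels" rule. Size ties break toward the component containing the larger
#' peak t, making the result deterministic. No minimum cluster size is
#' imposed.
#'
#' @param tmap Output of [localizer_contrast()] (columns `voxel`, `t`, `p`).
#' @param patch The `cortical_patch` supplying grid connectivity.
#' @param p_threshold Uncorrected one-sided p threshold (default 0.01).
#' @param zone Character vector of voxel ids defining the anatomical search
#'   zone; default all patch voxels. Must be non-empty.
#' @param name ROI label stored on the result (default `"roi"`).
#'
#' @return An `roi`: a tibble of the member voxels with their `t` and `p`,
#'   carrying attributes `name`, `zone`, and `p_threshold`.
#' @export
define_roi <- function(tmap, patch, p_threshold = 0.01,
                       zone = patch$voxel, name = "roi") {
  check_columns(tmap, c("voxel", "t", "p"), "tmap")
  check_number(p_threshold, "p_threshold", min = 0, strict = TRUE)
  if (length(zone) == 0) {
    stop_facegrad("`zone` must be non-empty.", "facegrad_invalid_argument")
  }
  supra <- tmap$voxel[!is.na(tmap$p) & tmap$p < p_threshold &
                        tmap$voxel %in% zone]
  if (length(supra) == 0) {
    stop_facegrad(
      sprintf("No voxel reaches p < %g inside the zone; ROI '%s' not found.",
              p_threshold, name),
      "facegrad_roi_not_found"
    )
  }
  comps <- connected_components(supra, patch_adjacency(patch))
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: component with the larger peak t
    peak <- vapply(best, function(i) {
      max(tmap$t[tmap$voxel %in% comps[[i]]], na.rm = TRUE)
    }, numeric(1))
    best <- best[which.max(peak)]
  }
  members <- comps[[best[1]]]
  out <- tmap[match(members, tmap$voxel), c("voxel", "t", "p")]
  out <- as_tibble(out)
  structure(out, class = c("roi", class(out)),
            name = name, zone = zone, p_threshold = p_threshold)
}

# Connected components over a voxel subset, given a full adjacency list.
# Iterative depth-first search; returns list of character vectors in
# deterministic (input) order.
connected_components <- function(voxels, adjacency) {
  inset <- stats::setNames(rep(TRUE, length(voxels)), voxels)
  visited <- stats::setNames(rep(FALSE, length(voxels)), voxels)
  comps <- list()
  for (v in voxels) {
    if (visited[[v]]) next
    stack <- v
    members <- character()
    while (length(stack) > 0) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (visited[[u]]) next
      visited[[u]] <- TRUE
      members <- c(members, u)
      nb <- adjacency[[u]]
      nb <- nb[!is.na(inset[nb]) & !visited[nb]]
      stack <- c(stack, nb)
    }
    comps[[length(comps) + 1]] <- members
  }
  comps
}

#' Exclude vein-contaminated voxels from an ROI
#'
#' Removes voxels whose percent signal change to the face condition is
#' strictly larger than the threshold (default 4%): abnormally large signal
#' changes at high field are characteristic of draining veins, not neural
#' tissue. A voxel at exactly the threshold is retained. Voxel order is
#' preserved.
#'
#' @param roi An `roi` from [define_roi()], or any data frame with a
#'   `voxel` column.
#' @param psc_face Data frame with columns `voxel`, `psc` giving the
#'   face-condition percent signal change; must cover every ROI voxel.
#' @param threshold PSC threshold in percent (default 4).
#'
#' @return The ROI tibble with vein voxels removed; attribute
#'   `n_veins_excluded` records how many were dropped. Removing every voxel
#'   raises an error.
#' @export
exclude_veins <- function(roi, psc_face, threshold = 4) {
  check_columns(roi, "voxel", "roi")
  check_columns(psc_face, c("voxel", "psc"), "psc_face")
  check_number(threshold, "threshold")
  psc <- psc_face$psc[match(roi$voxel, psc_face$voxel)]
  if (anyNA(psc)) {
    stop_facegrad("`psc_face` must provide a PSC for every ROI voxel.",
                  "facegrad_incomplete_data")
  }
  keep <- !(psc > threshold) # strict inequality: exactly 4.0 is retained
  if (!any(keep)) {
    stop_facegrad("Vein exclusion removed every voxel in the ROI.",
                  "facegrad_empty_roi")
  }
  out <- roi[keep, , drop = FALSE]
  attr(out, "name") <- attr(roi, "name")
  attr(out, "n_veins_excluded") <- sum(!keep)
  out
}
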