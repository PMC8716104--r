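#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' thresholds default to the conventional values used throughout the
#' package: localizer p < 0.01 uncorrected, vein exclusion at 4% signal
#' change, pRF inclusion at R-squared > 2%.
#'
#' The simulation defaults emulate the block-design experiment the package
#' is built around: 6 subjects, 8 runs of 16 s blocks (two per condition,
#' TR 2 s, fixation at start/middle/end), a 12 x 12 patch of 1.2 mm
#' vertices, an anatomical axis along the patch's long direction, an
#' eyes-posterior / mouth-anterior planted gradient, and a handful of vein
#' voxels.
#'
#' @param n_subjects Number of simulated subjects (default 6).
#' @param n_runs Runs per subject (default 8).
#' @param tr Repetition time in seconds (default 2).
#' @param conditions Condition names (default the seven-condition set).
#' @param slopes Named gradient slopes in PSC per mm (default eyes -0.1,
#'   mouth +0.1).
#' @param condition_means Named mean amplitudes in PSC.
#' @param patch_rows,patch_cols,spacing_mm Patch geometry.
#' @param beta_noise_sd Between-run beta noise SD (PSC units).
#' @param scan_noise_sd Scan-level noise SD for time-series simulation.
#' @param n_veins Number of planted vein voxels.
#' @param vein_psc Planted vein PSC (must exceed `vein_threshold`).
#' @param p_threshold Localizer threshold (uncorrected one-sided p).
#' @param localizer_fwhm_mm Gaussian smoothing (FWHM, mm) applied to the
#'   localizer-contrast condition maps only, before ROI definition
#'   (default 2; 0 disables). Main-experiment patterns are never smoothed.
#' @param vein_threshold Vein-exclusion PSC threshold in percent.
#' @param r2_threshold pRF inclusion threshold in percent.
#' @param bin_width Profile bin width in mm.
#' @param use_timeseries If `TRUE` (default) each run is simulated as a
#'   BOLD time series and passed through the GLM; if `FALSE` per-run betas
#'   are drawn directly (much faster; identical in distribution up to the
#'   GLM's sampling covariance).
#' @param general_condition Condition whose pattern is regressed out of the
#'   part patterns (default `"face"`).
#' @param seed Base integer seed.
#'
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(
    n_subjects = 6,
    n_runs = 8,
    tr = 2,
    conditions = c("eyes", "nose", "mouth", "hair", "chin", "face", "object"),
    slopes = c(eyes = -0.1, mouth = 0.1),
    condition_means = c(eyes = 1.2, nose = 0.8, mouth = 1.2, hair = 0.7,
                        chin = 0.7, face = 1.5, object = 0.5),
    patch_rows = 12, patch_cols = 12, spacing_mm = 1.2,
    beta_noise_sd = 0.3,
    scan_noise_sd = 1,
    n_veins = 4,
    vein_psc = 6,
    p_threshold = 0.01,
    localizer_fwhm_mm = 2,
    vein_threshold = 4,
    r2_threshold = 2,
    bin_width = 1.2,
    use_timeseries = TRUE,
    general_condition = "face",
    seed = 1L) {
  cfg <- as.list(environment())
  check_number(n_subjects, "n_subjects", min = 2)
  check_number(n_runs, "n_runs", min = 2)
  check_number(p_threshold, "p_threshold", min = 0, strict = TRUE)
  check_number(vein_threshold, "vein_threshold", min = 0)
  check_number(bin_width, "bin_width", min = 0, strict = TRUE)
  if (!all(c("eyes", "mouth", general_condition, "object") %in% conditions)) {
    stop_facegrad(
      "`conditions` must include eyes, mouth, object and the general condition.",
      "facegrad_invalid_argument"
    )
  }
  if (vein_psc <= vein_threshold) {
    stop_facegrad("`vein_psc` must exceed `vein_threshold`.",
                  "facegrad_invalid_argument")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic subjects
#'
#' Executes simulate -> GLM -> ROI definition -> vein exclusion ->
#' pattern normalization and general-pattern removal -> axis projection ->
#' gradient correlation -> group statistics for every simulated subject,
#' and returns per-subject results, the group test, group-averaged
#' profiles, and a provenance manifest. Outputs are a pure function of the
#' configuration (including its seed).
#'
#' @param config A [pipeline_config()].
#'
#' @return A `facegrad_report`: list with elements `per_subject` (tibble:
#'   subject, gradient r on the normalized eyes-mouth contrast,
#'   residual-based r, split-half reliability, ROI size, veins excluded),
#'   `group` (a `gradient_stats`), `profiles` (per-subject
#'   `spatial_profile` rows bound with a `subject` column), `amplitudes`
#'   (subject x condition mean ROI amplitudes), and `manifest`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(n_subjects = 2, use_timeseries = FALSE))
#' tidy(rep$group)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    analyze_subject(config, subject = s,
                    seed = as.integer(config$seed) + 1000L * s)
  })
  per_subject <- bind_rows(lapply(subjects, `[[`, "summary"))
  profiles <- bind_rows(lapply(subjects, `[[`, "profile"))
  amplitudes <- bind_rows(lapply(subjects, `[[`, "amplitudes"))
  group <- group_onesample_t(per_subject$gradient_r)
  manifest <- list(
    config = unclass(config),
    thresholds = list(p = config$p_threshold, vein_psc = config$vein_threshold,
                      r2_pct = config$r2_threshold),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("facegrad")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(
    list(per_subject = per_subject, group = group, profiles = profiles,
         amplitudes = amplitudes, manifest = manifest),
    class = "facegrad_report"
  )
}

# One subject: simulate, estimate, define ROI, remove shared pattern,
# project, correlate. Returns summary row + per-condition profile.
analyze_subject <- function(config, subject, seed) {
  patch <- make_patch(config$patch_rows, config$patch_cols,
                      spacing_mm = config$spacing_mm)
  axis <- anatomical_axis(rbind(
    c(0, mean(range(patch$y_mm))),
    c(max(patch$x_mm), mean(range(patch$y_mm)))
  ))
  set.seed(seed)
  vein_ids <- sample(patch$voxel, config$n_veins)
  truth <- ground_truth(
    patch, axis, slopes = config$slopes,
    condition_means = config$condition_means,
    noise_sd = config$beta_noise_sd,
    vein_ids = vein_ids, vein_psc = config$vein_psc
  )

  # per-run beta estimates (via the GLM, or drawn directly)
  betas_by_run <- bind_rows(lapply(seq_len(config$n_runs), function(r) {
    run_seed <- seed + r
    planted <- simulate_betas(truth, config$conditions, seed = run_seed)
    if (config$use_timeseries) {
      blocks <- standard_run_blocks(config$conditions, run = r)
      design <- build_design(blocks, tr = config$tr,
                             n_scans = run_n_scans(blocks, tr = config$tr))
      y <- simulate_timeseries(design, planted,
                               noise_sd = config$scan_noise_sd,
                               seed = run_seed, ar1 = truth$ar1)
      est <- fit_glm(y, design)
    } else {
      est <- planted
    }
    est$run <- r
    est
  }))

  loc_betas <- filter(betas_by_run, .data$condition %in% c("face", "object"))
  if (config$localizer_fwhm_mm > 0) {
    loc_betas <- loc_betas |>
      group_by(.data$run, .data$condition) |>
      mutate(beta = {
        sm <- smooth_patch_values(
          patch, .data$beta[match(patch$voxel, .data$voxel)],
          fwhm_mm = config$localizer_fwhm_mm
        )
        sm[match(.data$voxel, patch$voxel)]
      }) |>
      ungroup()
  }
  tmap <- localizer_contrast(loc_betas, "face", "object")
  roi <- define_roi(tmap, patch, p_threshold = config$p_threshold,
                    name = paste0("S", subject))

  mean_betas <- betas_by_run |>
    group_by(.data$voxel, .data$condition) |>
    summarise(beta = mean(.data$beta), psc = mean(.data$psc),
              .groups = "drop")
  psc_face <- mean_betas |>
    filter(.data$condition == "face") |>
    select("voxel", "psc")
  roi <- exclude_veins(roi, psc_face, threshold = config$vein_threshold)

  roi_betas <- semi_join(mean_betas, roi, by = "voxel")
  pattern_of <- function(cond) {
    p <- roi_betas |>
      filter(.data$condition == cond) |>
      select("voxel", value = "beta")
    attr(p, "condition") <- cond
    p
  }
  eyes_n <- normalize_pattern(pattern_of("eyes"))
  mouth_n <- normalize_pattern(pattern_of("mouth"))
  contrast <- contrast_map(eyes_n, mouth_n)

  general <- pattern_of(config$general_condition)
  eyes_res <- tidy(regress_out(pattern_of("eyes"), general))
  mouth_res <- tidy(regress_out(pattern_of("mouth"), general))

  proj <- project_to_axis(semi_join(patch, roi, by = "voxel"), axis)
  pos <- proj[, c("voxel", "position_mm")]

  grad_data <- left_join(contrast, pos, by = "voxel")
  gradient_r <- gradient_correlation(grad_data)
  res_diff <- tibble(voxel = eyes_res$voxel,
                     value = eyes_res$value -
                       mouth_res$value[match(eyes_res$voxel, mouth_res$voxel)])
  residual_r <- gradient_correlation(left_join(res_diff, pos, by = "voxel"))

  split_r <- split_half_reliability(
    semi_join(betas_by_run, roi, by = "voxel"), "eyes", "mouth"
  )

  profile <- build_profile(
    bind_rows(
      left_join(mutate(eyes_res, condition = "eyes"), pos, by = "voxel"),
      left_join(mutate(mouth_res, condition = "mouth"), pos, by = "voxel")
    ),
    bin_width = config$bin_width
  )
  profile$subject <- subject

  amplitudes <- roi_betas |>
    group_by(.data$condition) |>
    summarise(amplitude = mean(.data$beta), .groups = "drop") |>
    mutate(subject = subject)

  list(
    summary = tibble(
      subject = subject,
      gradient_r = gradient_r,
      residual_r = residual_r,
      split_half_r = split_r,
      roi_size = nrow(roi),
      n_veins_excluded = attr(roi, "n_veins_excluded")
    ),
    profile = profile,
    amplitudes = amplitudes
  )
}

#' @export
print.facegrad_report <- function(x, ...) {
  cat("<facegrad_report>\n")
  cat(sprintf("  subjects: %d   mean gradient r: %.3f\n",
              nrow(x$per_subject), mean(x$per_subject$gradient_r)))
  print(x$group)
  invisible(x)
}

#' Summarise a pipeline report
#'
#' Produces the human-readable summary of a pipeline run: the per-subject
#' table, the group test in the conventional
#' `t(df) = ..., p = ..., Cohen's d = ...` style, and (optionally) profile
#' plots. Statistics are recomputed from the stored per-subject values, not
#' cached strings.
#'
#' @param report A `facegrad_report` from [run_pipeline()].
#' @param plots Also build ggplot profile plots (default TRUE).
#'
#' @return A list with `summary_text` (character vector), `per_subject`,
#'   `group` (tidy tibble), and `profile_plot` (a ggplot or `NULL`).
#' @export
make_report <- function(report, plots = TRUE) {
  stopifnot(inherits(report, "facegrad_report"))
  g <- report$group
  lines <- c(
    sprintf("Subjects analysed: %d", nrow(report$per_subject)),
    sprintf("Per-subject gradient r (eyes - mouth vs position): %s",
            paste(sprintf("%.3f", report$per_subject$gradient_r),
                  collapse = ", ")),
    sprintf("Group test: t(%d) = %.2f, p = %.4g, Cohen's d = %.2f",
            g$df, g$t, g$p, g$cohens_d),
    sprintf("Split-half reliability (median): %.3f",
            stats::median(report$per_subject$split_half_r)),
    sprintf("Thresholds applied: localizer p < %g, vein PSC > %g%%",
            report$manifest$thresholds$p,
            report$manifest$thresholds$vein_psc),
    sprintf("Design constants: %g s blocks, TR %g s, seed %d",
            16, report$manifest$config$tr, report$manifest$seed)
  )
  profile_plot <- if (plots && nrow(report$profiles) > 0) {
    plot_profiles(report$profiles)
  }
  list(summary_text = lines, per_subject = report$per_subject,
       group = tidy(g), profile_plot = profile_plot)
}
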