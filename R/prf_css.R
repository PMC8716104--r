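#' Compressive spatial summation (CSS) pRF parameters
#'
#' The CSS population receptive field model: an isotropic 2-D Gaussian over
#' the visual field whose overlap with the stimulus aperture is raised to a
#' static power-law exponent, scaled by a gain, and convolved with the HRF.
#' `n < 1` gives compressive (sub-linear) spatial summation, the typical
#' regime in higher visual areas.
#'
#' @param x,y Receptive field centre in degrees of visual angle.
#' @param sigma Gaussian standard deviation in degrees (> 0).
#' @param n Power-law exponent (> 0); 1 is linear summation.
#' @param gain Response gain in signal units.
#' @param r2 Fit quality, percent of variance explained (only set by
#'   [fit_css()]).
#'
#' @return A one-row `css_params` tibble.
#' @export
css_params <- function(x = 0, y = 0, sigma = 1, n = 0.5, gain = 1,
                       r2 = NA_real_) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_facegrad("`sigma` must be positive and finite.",
                  "facegrad_invalid_argument")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n <= 0)) {
    stop_facegrad("`n` must be positive and finite.",
                  "facegrad_invalid_argument")
  }
  out <- tibble(x = x, y = y, sigma = sigma, n = n, gain = gain, r2 = r2)
  structure(out, class = c("css_params", class(out)))
}

# unit-sum isotropic Gaussian over the aperture pixel grid
css_gaussian <- function(apertures, x, y, sigma) {
  g <- exp(-((apertures$x - x)^2 + (apertures$y - y)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Predicted CSS time series for one voxel
#'
#' `r(t) = gain * (sum_pixels frame_t * G)^n`, with G the unit-sum Gaussian
#' at (`x`, `y`, `sigma`), convolved with the gamma HRF sampled at the
#' stack's TR and truncated to the run length. With full-field frames and
#' `n = 1` the pre-convolution response equals the gain exactly, because the
#' Gaussian sums to one over the grid.
#'
#' @param apertures An `aperture_stack`.
#' @param p A `css_params` row (or anything with `$x`, `$y`, `$sigma`,
#'   `$n`, `$gain`).
#' @param hrf An [hrf_params()] object.
#'
#' @return Numeric vector, one value per aperture frame.
#' @export
css_response <- function(apertures, p, hrf = hrf_params()) {
  stopifnot(inherits(apertures, "aperture_stack"))
  if (nrow(apertures$frames) == 0) {
    stop_facegrad("Aperture stack has no frames.", "facegrad_invalid_argument")
  }
  check_number(p$sigma, "sigma", min = 0, strict = TRUE)
  check_number(p$n, "n", min = 0, strict = TRUE)
  g <- css_gaussian(apertures, p$x, p$y, p$sigma)
  neural <- p$gain * as.vector(apertures$frames %*% g)^p$n
  convolve_with_hrf(neural, apertures$tr, hrf)
}

convolve_with_hrf <- function(neural, tr, hrf) {
  n <- length(neural)
  h <- gamma_hrf((seq_len(n) - 1) * tr, hrf)
  convolve(neural, rev(h), type = "open")[seq_len(n)]
}

#' Simulate CSS pRF voxel time series
#'
#' Forward model for the retinotopy control analysis: each voxel's series is
#' its [css_response()] plus i.i.d. Gaussian noise. Every receptive field
#' centre must lie within the stimulated field.
#'
#' @param apertures An `aperture_stack`.
#' @param params A `css_params` tibble, one row per voxel.
#' @param noise_sd Noise SD (>= 0).
#' @param seed Integer seed; output is reproducible.
#'
#' @return Matrix frames x voxels (columns `v1`, `v2`, ...).
#' @export
simulate_css_voxels <- function(apertures, params, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(apertures, "aperture_stack"))
  check_number(noise_sd, "noise_sd", min = 0)
  check_columns(params, c("x", "y", "sigma", "n", "gain"), "params")
  if (nrow(params) == 0) {
    stop_facegrad("`params` must contain at least one voxel.",
                  "facegrad_invalid_argument")
  }
  if (any(params$sigma <= 0)) {
    stop_facegrad("pRF sizes must be positive.", "facegrad_invalid_argument")
  }
  if (any(params$x^2 + params$y^2 > apertures$radius_deg^2)) {
    stop_facegrad("Every pRF centre must lie within the stimulated field.",
                  "facegrad_invalid_argument")
  }
  clean <- vapply(seq_len(nrow(params)), function(i) {
    css_response(apertures, params[i, ])
  }, numeric(nrow(apertures$frames)))
  set.seed(as.integer(seed))
  noisy <- clean + matrix(rnorm(length(clean), 0, noise_sd),
                          nrow = nrow(clean))
  colnames(noisy) <- paste0("v", seq_len(ncol(noisy)))
  noisy
}

# Precompute HRF-convolved predictions for a grid of candidate parameters.
# Shared across voxels; the expensive frames %*% G products are done once.
css_candidate_grid <- function(apertures, hrf,
                               x_grid, y_grid, sigma_grid, n_grid) {
  cand <- expand.grid(x = x_grid, y = y_grid, sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  G <- vapply(seq_len(nrow(cand)), function(i) {
    css_gaussian(apertures, cand$x[i], cand$y[i], cand$sigma[i])
  }, numeric(length(apertures$x)))
  overlap <- apertures$frames %*% G # frames x candidates
  preds <- list()
  tab <- list()
  for (n_exp in n_grid) {
    P <- overlap^n_exp
    P <- apply(P, 2, convolve_with_hrf, tr = apertures$tr, hrf = hrf)
    preds[[length(preds) + 1]] <- P
    tab[[length(tab) + 1]] <- transform(cand, n = n_exp)
  }
  list(pred = do.call(cbind, preds), cand = do.call(rbind, tab))
}

#' Fit the CSS pRF model to voxel time series
#'
#' Two-stage estimation per voxel: a coarse grid search over centre,
#' size, and exponent (gain and offset by least squares at each candidate,
#' so the grid step reduces to picking the candidate with the highest
#' squared correlation), followed by bounded quasi-Newton refinement of
#' `(x, y, sigma, n)`. Fit quality is the coefficient of determination
#' against the mean-only model, in percent.
#'
#' Default search ranges are `x, y` in `[-radius, radius]`, `sigma` in
#' `[0.1, 8]` degrees, and grid exponents `{0.25, 0.5, 0.75, 1}` with
#' refinement allowed in `[0.05, 2]`.
#'
#' @param series Numeric matrix frames x voxels (a vector is treated as one
#'   voxel).
#' @param apertures The `aperture_stack` the series were recorded under.
#' @param hrf An [hrf_params()] object.
#' @param grid_points Candidate centres per axis in the coarse grid
#'   (default 9).
#' @param sigma_grid Candidate sizes in degrees.
#' @param n_grid Candidate exponents for the grid stage.
#' @param refine Run the local refinement stage (default TRUE).
#' @param refine_starts Number of distinct top grid candidates used as
#'   refinement starting points (default 5); the size-exponent trade-off of
#'   the model creates local optima that a single start can fall into.
#'
#' @return A `css_params` tibble with one row per voxel (column `voxel`
#'   prepended) and fitted `x`, `y`, `sigma`, `n`, `gain`, `r2` (percent).
#'   A flat (zero-variance) series yields `gain = 0`, `r2 = 0` rather than
#'   an error.
#' @export
fit_css <- function(series, apertures, hrf = hrf_params(),
                    grid_points = 9,
                    sigma_grid = c(0.25, 0.5, 1, 2, 4, 8),
                    n_grid = c(0.25, 0.5, 0.75, 1),
                    refine = TRUE, refine_starts = 5) {
  stopifnot(inherits(apertures, "aperture_stack"))
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  if (nrow(series) != nrow(apertures$frames)) {
    stop_facegrad(
      sprintf("Series has %d frames but the aperture stack has %d.",
              nrow(series), nrow(apertures$frames)),
      "facegrad_invalid_argument"
    )
  }
  if (is.null(colnames(series))) {
    colnames(series) <- paste0("v", seq_len(ncol(series)))
  }
  r <- apertures$radius_deg
  centers <- seq(-r, r, length.out = grid_points)
  grid <- css_candidate_grid(apertures, hrf, centers, centers,
                             sigma_grid, n_grid)
  P <- grid$pred
  P_c <- sweep(P, 2, colMeans(P)) # centred predictions
  P_ss <- colSums(P_c^2)

  fits <- lapply(seq_len(ncol(series)), function(j) {
    yv <- series[, j]
    y_c <- yv - mean(yv)
    ss_tot <- sum(y_c^2)
    if (ss_tot == 0) {
      return(tibble(voxel = colnames(series)[j], x = 0, y = 0, sigma = 1,
                    n = 1, gain = 0, r2 = 0))
    }
    # R^2 of y ~ intercept + gain * pred is the squared correlation
    num <- as.vector(crossprod(P_c, y_c))
    r2_grid <- ifelse(P_ss > 0, num^2 / (P_ss * ss_tot), 0)
    best <- which.max(r2_grid)
    par <- as.numeric(grid$cand[best, c("x", "y", "sigma", "n")])

    obj <- function(par) {
      g <- css_gaussian(apertures, par[1], par[2], par[3])
      pred <- convolve_with_hrf(
        as.vector(apertures$frames %*% g)^par[4], apertures$tr, hrf)
      p_c <- pred - mean(pred)
      ss <- sum(p_c^2)
      if (ss == 0) return(ss_tot)
      ss_tot - sum(p_c * y_c)^2 / ss # residual SS after LS gain + intercept
    }
    if (refine) {
      ord <- order(r2_grid, decreasing = TRUE)
      starts <- grid$cand[utils::head(ord, refine_starts),
                          c("x", "y", "sigma", "n"), drop = FALSE]
      best_val <- obj(par)
      for (s in seq_len(nrow(starts))) {
        opt <- try(stats::optim(
          as.numeric(starts[s, ]), obj, method = "L-BFGS-B",
          lower = c(-r, -r, 0.05, 0.05), upper = c(r, r, 8, 2),
          control = list(maxit = 400, factr = 1e4)
        ), silent = TRUE)
        if (!inherits(opt, "try-error") && is.finite(opt$value) &&
            opt$value < best_val) {
          best_val <- opt$value
          par <- opt$par
        }
      }
    }
    g <- css_gaussian(apertures, par[1], par[2], par[3])
    pred <- convolve_with_hrf(
      as.vector(apertures$frames %*% g)^par[4], apertures$tr, hrf)
    p_c <- pred - mean(pred)
    ss <- sum(p_c^2)
    gain <- if (ss > 0) sum(p_c * y_c) / ss else 0
    res <- y_c - gain * p_c
    r2 <- 100 * (1 - sum(res^2) / ss_tot)
    tibble(voxel = colnames(series)[j], x = par[1], y = par[2],
           sigma = par[3], n = par[4], gain = gain, r2 = r2)
  })
  out <- bind_rows(fits)
  structure(out, class = c("css_params", class(out)))
}

#' Filter pRF fits by variance explained
#'
#' Keeps fits whose R-squared is strictly higher than the threshold
#' (default 2%), the conventional inclusion rule for pRF results; a fit at
#' exactly the threshold is removed.
#'
#' @param fits A `css_params` tibble with an `r2` column (percent).
#' @param threshold_pct Threshold in percent (default 2).
#'
#' @return The filtered tibble.
#' @export
filter_by_r2 <- function(fits, threshold_pct = 2) {
  check_columns(fits, "r2", "fits")
  check_number(threshold_pct, "threshold_pct")
  fits[fits$r2 > threshold_pct, , drop = FALSE]
}
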