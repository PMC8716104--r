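#' Fit a voxelwise GLM and return condition betas
#'
#' Ordinary least-squares fit of every voxel time course against a
#' block-design matrix. Returns one beta weight per voxel and condition plus
#' the percent signal change (PSC), computed with the standard convention
#' `psc = 100 * beta / baseline` where `baseline` is the voxel's intercept
#' estimate. PSC is `NA` where the baseline estimate is not positive.
#'
#' The design must be full rank: a rank-deficient matrix raises an explicit
#' error instead of silently falling back to a pseudo-inverse, because a
#' deficient block design almost always signals a mis-specified condition
#' table.
#'
#' @param series Voxel time series: either a numeric matrix of dimension
#'   `n_scans` x `n_voxels` (column names taken as voxel ids) or a long data
#'   frame with columns `voxel`, `scan`, `bold`.
#' @param design A `design_matrix` from [build_design()].
#'
#' @return A `betamap`: a tibble with columns `voxel`, `condition`, `beta`,
#'   `baseline`, `psc`, one row per voxel x condition. Nuisance columns
#'   (intercept, drift) are folded into `baseline` / dropped, not reported as
#'   conditions.
#' @examples
#' blocks <- data.frame(condition = "eyes", onset = 16, duration = 16)
#' d <- build_design(blocks, tr = 2, n_scans = 40)
#' y <- d$matrix %*% c(1.5, 100)
#' fit_glm(y, d)
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as_series_matrix(series, design$n_scans)
  X <- design$matrix

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_facegrad(
      sprintf("Design matrix is rank deficient (rank %d < %d columns).",
              qx$rank, ncol(X)),
      "facegrad_rank_error"
    )
  }
  B <- qr.coef(qx, Y)

  baseline <- B["baseline", ]
  conds <- design$conditions
  out <- tibble(
    voxel = rep(colnames(Y), each = length(conds)),
    condition = rep(conds, times = ncol(Y)),
    beta = as.vector(B[conds, , drop = FALSE]),
    baseline = rep(unname(baseline), each = length(conds))
  )
  out$psc <- ifelse(out$baseline > 0, 100 * out$beta / out$baseline, NA_real_)
  new_betamap(out)
}

new_betamap <- function(df) {
  structure(as_tibble(df), class = c("betamap", class(as_tibble(df))))
}

#' @export
print.betamap <- function(x, ...) {
  cat(sprintf("<betamap> %d voxels x %d conditions\n",
              length(unique(x$voxel)), length(unique(x$condition))))
  NextMethod()
}

# Coerce time series input (matrix or long tibble) to n_scans x n_voxels
# matrix with voxel ids as column names.
as_series_matrix <- function(series, n_scans) {
  if (is.data.frame(series)) {
    check_columns(series, c("voxel", "scan", "bold"), "series")
    wide <- tidyr::pivot_wider(
      series[, c("voxel", "scan", "bold")],
      names_from = "voxel", values_from = "bold"
    )
    wide <- wide[order(wide$scan), , drop = FALSE]
    Y <- as.matrix(wide[, setdiff(names(wide), "scan"), drop = FALSE])
  } else if (is.numeric(series)) {
    Y <- as.matrix(series)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("v", seq_len(ncol(Y)))
  } else {
    stop_facegrad("`series` must be a numeric matrix or a long data frame.",
                  "facegrad_invalid_argument")
  }
  if (nrow(Y) != n_scans) {
    stop_facegrad(
      sprintf("Series has %d scans but the design expects %d.",
              nrow(Y), n_scans),
      "facegrad_invalid_argument"
    )
  }
  storage.mode(Y) <- "double"
  Y
}

#' GLM residuals for diagnostic checks
#'
#' Returns the residual matrix of the voxelwise OLS fit; residuals are
#' orthogonal to every design column up to numerical precision.
#'
#' @inheritParams fit_glm
#' @return `n_scans` x `n_voxels` matrix of residuals.
#' @export
glm_residuals <- function(series, design) {
  Y <- as_series_matrix(series, design$n_scans)
  X <- design$matrix
  qx <- qr(X)
  Y - X %*% qr.coef(qx, Y)
}

#' Analytic sampling covariance of GLM betas
#'
#' For white scan noise of standard deviation `noise_sd`, OLS betas have
#' covariance `noise_sd^2 (X'X)^-1`. Used to express planted effect sizes
#' as signal-to-noise ratios relative to the estimator's own sampling
#' noise.
#'
#' @param design A `design_matrix`.
#' @param noise_sd Scan noise SD.
#' @return Covariance matrix over all design columns.
#' @export
glm_beta_cov <- function(design, noise_sd) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  noise_sd^2 * solve(crossprod(X))
}
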