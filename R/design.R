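#' Build a block-design GLM design matrix
#'
#' Turns a table of stimulus blocks into a design matrix for ordinary
#' least-squares estimation. Each condition gets one regressor: a boxcar
#' (1 while a block of that condition is on screen, 0 otherwise) sampled on
#' the scan grid `t_k = (k - 1) * tr`, convolved with the gamma HRF and
#' truncated to the run length. An intercept column models the baseline
#' signal; optional Legendre-style polynomial drift columns can be added.
#'
#' Overlapping blocks of the same condition sum (their boxcars add), which
#' matches the linear-systems convention and is occasionally useful for
#' jittered designs.
#'
#' @param blocks Data frame with columns `condition` (character), `onset`
#'   and `duration` (seconds). Onsets must be >= 0 and every block must end
#'   within the run.
#' @param tr Repetition time in seconds (> 0).
#' @param n_scans Number of volumes in the run (>= 1).
#' @param hrf An [hrf_params()] object used for convolution.
#' @param drift_order Integer >= 0; number of polynomial drift columns
#'   (beyond the intercept) to append. Default 0: baseline intensity is
#'   assumed already normalized upstream.
#'
#' @return An object of class `design_matrix`: a list with elements
#'   `matrix` (`n_scans` x (conditions + 1 + drift_order) numeric matrix with
#'   named columns, intercept named `"baseline"`), `conditions` (ordered
#'   condition names), `tr`, `n_scans`, `blocks` (the input tibble), and
#'   `hrf`.
#' @examples
#' blocks <- data.frame(condition = "eyes", onset = 16, duration = 16)
#' d <- build_design(blocks, tr = 2, n_scans = 40)
#' dim(d$matrix)
#' @export
build_design <- function(blocks, tr, n_scans, hrf = hrf_params(),
                         drift_order = 0L) {
  check_number(tr, "tr", min = 0, strict = TRUE)
  check_number(n_scans, "n_scans", min = 1)
  check_number(drift_order, "drift_order", min = 0)
  stopifnot(inherits(hrf, "hrf_params"))
  blocks <- as_tibble(blocks)
  if (nrow(blocks) > 0) {
    check_columns(blocks, c("condition", "onset", "duration"), "blocks")
    if (any(blocks$onset < 0)) {
      stop_facegrad("Block onsets must be >= 0.", "facegrad_invalid_argument")
    }
    if (any(blocks$duration <= 0)) {
      stop_facegrad("Block durations must be > 0.", "facegrad_invalid_argument")
    }
    run_end <- n_scans * tr
    if (any(blocks$onset + blocks$duration > run_end + 1e-9)) {
      stop_facegrad(
        sprintf("All blocks must end within the run (%g s).", run_end),
        "facegrad_invalid_argument"
      )
    }
  }

  t_grid <- (seq_len(n_scans) - 1) * tr
  conditions <- if (nrow(blocks) > 0) unique(blocks$condition) else character()

  h <- gamma_hrf(t_grid, hrf)
  cols <- lapply(conditions, function(cond) {
    boxcar <- rep(0, n_scans)
    rows <- blocks[blocks$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      on <- t_grid >= rows$onset[i] - 1e-9 &
        t_grid < rows$onset[i] + rows$duration[i] - 1e-9
      boxcar <- boxcar + as.numeric(on)
    }
    # discrete convolution on the TR grid, truncated to the run
    convolve(boxcar, rev(h), type = "open")[seq_len(n_scans)]
  })
  X <- do.call(cbind, c(cols, list(rep(1, n_scans))))
  colnames(X) <- c(conditions, "baseline")
  if (drift_order > 0) {
    tt <- seq(-1, 1, length.out = n_scans)
    drift <- vapply(seq_len(drift_order), function(k) tt^k, numeric(n_scans))
    colnames(drift) <- paste0("drift", seq_len(drift_order))
    X <- cbind(X, drift)
  }

  structure(
    list(matrix = X, conditions = conditions, tr = tr, n_scans = n_scans,
         blocks = blocks, hrf = hrf),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d regressors (TR %g s)\n",
              x$n_scans, ncol(x$matrix), x$tr))
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Standard block layout for one experimental run
#'
#' Convenience constructor for the block table of one run of the main
#' experiment emulated by the synthetic-data module: `n_reps` 16 s blocks of
#' each condition, separated by 16 s fixation at the beginning, the middle,
#' and the end of the run, with condition order rotated deterministically
#' per run.
#'
#' @param conditions Character vector of condition names.
#' @param n_reps Blocks per condition (default 2).
#' @param block_s Block duration in seconds (default 16).
#' @param fixation_s Fixation duration at start/middle/end (default 16).
#' @param run Run index (>= 1); rotates the block order so runs differ.
#'
#' @return A tibble with columns `condition`, `onset`, `duration`. Use
#'   [run_n_scans()] to get the scan count covering the run.
#' @export
standard_run_blocks <- function(conditions, n_reps = 2, block_s = 16,
                                fixation_s = 16, run = 1L) {
  stopifnot(length(conditions) >= 1, n_reps >= 1)
  order <- rep(conditions, n_reps)
  # deterministic rotation so block order varies across runs
  shift <- (run - 1L) %% length(order)
  order <- c(tail(order, length(order) - shift), head(order, shift))
  n_blocks <- length(order)
  half <- ceiling(n_blocks / 2)
  onsets <- numeric(n_blocks)
  t <- fixation_s
  for (i in seq_len(n_blocks)) {
    if (i == half + 1) t <- t + fixation_s # mid-run fixation
    onsets[i] <- t
    t <- t + block_s
  }
  tibble(condition = order, onset = onsets, duration = block_s)
}

#' Number of scans for a standard run
#'
#' @param blocks Block table from [standard_run_blocks()].
#' @param tr Repetition time in seconds.
#' @param fixation_s Trailing fixation in seconds.
#' @return Integer scan count covering the run.
#' @export
run_n_scans <- function(blocks, tr = 2, fixation_s = 16) {
  as.integer(ceiling((max(blocks$onset + blocks$duration) + fixation_s) / tr))
}
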