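#' Gamma haemodynamic response parameters
#'
#' Bundles the two parameters of the gamma-variate haemodynamic response
#' function (HRF) used throughout the package: the onset delay `delta` and
#' the time constant `tau`, both in seconds. The defaults (`delta = 2.25`,
#' `tau = 1.25`) give a response peaking at `delta + 2 * tau = 4.75` s, the
#' standard setting for block-design analyses of 2 s TR data.
#'
#' @param delta Onset delay in seconds; the response is identically zero for
#'   `t < delta`. Must be >= 0.
#' @param tau Time constant in seconds; controls the width of the response.
#'   Must be > 0.
#'
#' @return An object of class `hrf_params`: a named list with elements
#'   `delta` and `tau`.
#' @examples
#' hrf_params()
#' hrf_params(delta = 2, tau = 1)
#' @export
hrf_params <- function(delta = 2.25, tau = 1.25) {
  check_number(delta, "delta", min = 0)
  check_number(tau, "tau", min = 0, strict = TRUE)
  structure(list(delta = delta, tau = tau), class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf("<hrf_params> gamma HRF: delta = %g s, tau = %g s (peak at %g s)\n",
              x$delta, x$tau, x$delta + 2 * x$tau))
  invisible(x)
}

#' Evaluate the gamma haemodynamic response function
#'
#' Computes the two-parameter gamma-variate HRF
#' `h(t) = ((t - delta) / tau)^2 * exp(-(t - delta) / tau)` for `t >= delta`
#' and 0 otherwise, rescaled so its peak value is exactly 1. The exponent is
#' fixed at 2, so the peak occurs at `t = delta + 2 * tau`.
#'
#' The unit-peak scaling is a convention: it makes GLM beta weights carry the
#' peak amplitude of the evoked response. Unit-area scaling would only rescale
#' all betas by a common factor and is available via `scale = "area"`.
#'
#' @param t Numeric vector of time points in seconds (need not be sorted).
#' @param params An [hrf_params()] object.
#' @param scale Either `"peak"` (default; maximum of the continuous function
#'   is 1) or `"area"` (continuous function integrates to 1).
#'
#' @return Numeric vector of HRF values, same length as `t`.
#' @examples
#' t <- seq(0, 24, by = 0.05)
#' h <- gamma_hrf(t)
#' t[which.max(h)] # 4.75 = delta + 2 * tau
#' @export
gamma_hrf <- function(t, params = hrf_params(), scale = c("peak", "area")) {
  scale <- match.arg(scale)
  stopifnot(inherits(params, "hrf_params"))
  if (!is.numeric(t)) {
    stop_facegrad("`t` must be numeric.", "facegrad_invalid_argument")
  }
  x <- (t - params$delta) / params$tau
  h <- ifelse(t >= params$delta, x^2 * exp(-x), 0)
  if (scale == "peak") {
    # continuous-time peak value of x^2 exp(-x) is at x = 2
    h / (4 * exp(-2))
  } else {
    # integral of x^2 exp(-x) over x >= 0 is Gamma(3) = 2; dt = tau dx
    h / (2 * params$tau)
  }
}
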