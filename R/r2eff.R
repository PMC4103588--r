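# Conversion of peak intensities to effective relaxation rates.

#' Two-point R2eff for constant-time CPMG experiments
#'
#' `R2eff = -ln(I / I_ref) / T`, the standard conversion for constant-time
#' experiments with a reference spectrum. A negative rate (intensity above the
#' reference) is allowed but flagged with a warning.
#'
#' @param i_ref Reference-spectrum intensity (`> 0`).
#' @param i Intensity at the dispersion point (`> 0`).
#' @param relax_time_T Constant relaxation period in s (`> 0`).
#' @return Rate in 1/s.
#' @examples
#' calc_r2eff_two_point(1e6, 3.6787944e5, 0.04)  # 25
#' @export
calc_r2eff_two_point <- function(i_ref, i, relax_time_T) {
  if (any(i_ref <= 0) || any(i <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (any(relax_time_T <= 0)) stop("relax_time_T must be > 0", call. = FALSE)
  r <- -log(i / i_ref) / relax_time_T
  if (any(r < 0)) {
    warning("negative R2eff (intensity above reference) at ", sum(r < 0),
            " point(s)", call. = FALSE)
  }
  r
}

#' First-order error propagation for the two-point R2eff
#'
#' `sigma_R = sqrt((sigma/I)^2 + (sigma_ref/I_ref)^2) / T`.
#'
#' @param i_ref,i Intensities (`> 0`).
#' @param sigma_ref,sigma Intensity standard deviations (`>= 0`).
#' @param relax_time_T Constant relaxation period in s (`> 0`).
#' @return One standard deviation of R2eff, in 1/s.
#' @export
propagate_r2eff_error <- function(i_ref, i, sigma_ref, sigma, relax_time_T) {
  if (any(i_ref <= 0) || any(i <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (any(relax_time_T <= 0)) stop("relax_time_T must be > 0", call. = FALSE)
  if (any(sigma_ref < 0) || any(sigma < 0)) {
    stop("sigmas must be >= 0", call. = FALSE)
  }
  sqrt((sigma / i)^2 + (sigma_ref / i_ref)^2) / relax_time_T
}

#' Exponential rate from a multi-point intensity decay
#'
#' Fits `I(t) = I0 * exp(-R t)` by weighted least squares on the log scale,
#' with delta-method weights `(I_i / sigma_i)^2`, for experiments that sample
#' several relaxation delays rather than a constant-time pair. Returns the
#' rate and its covariance-based standard error.
#'
#' @param times Relaxation delays in s (at least two distinct values).
#' @param intensities Peak intensities (`> 0`), one per delay.
#' @param errors Intensity standard deviations (`> 0`), one per delay.
#' @return A list with elements `value` (R, 1/s), `error` (s.d. of R) and
#'   `i0` (fitted initial intensity).
#' @export
calc_r2eff_exponential_free <- function(times, intensities, errors) {
  stopifnot(length(times) == length(intensities),
            length(times) == length(errors))
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (any(intensities <= 0)) stop("intensities must be positive", call. = FALSE)
  if (any(errors <= 0)) stop("errors must be positive", call. = FALSE)
  if (length(unique(times)) < 2) {
    stop("degenerate input: all times equal", call. = FALSE)
  }
  y <- log(intensities)
  w <- (intensities / errors)^2
  X <- cbind(1, -times)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  covb <- solve(XtWX)  # errors are absolute, not rescaled by residuals
  list(value = beta[2], error = sqrt(covb[2, 2]), i0 = exp(beta[1]))
}
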