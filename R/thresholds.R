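#' Hard thresholding
#'
#' Keep-or-kill shrinkage: coefficients with magnitude at least `lam` are kept
#' unchanged, the rest are set to zero. The boundary `|w| == lam` is kept.
#'
#' @param w numeric vector, matrix, or array of coefficients.
#' @param lam threshold, a single value >= 0.
#' @return Object of the same shape as `w`.
#' @export
hard_threshold <- function(w, lam) {
  check_lambda(lam)
  w * (abs(w) >= lam)
}

#' Soft thresholding
#'
#' Shrinks every surviving coefficient toward zero by `lam`:
#' `sgn(w) * (|w| - lam)` where `|w| >= lam`, zero elsewhere.
#'
#' @inheritParams hard_threshold
#' @return Object of the same shape as `w`.
#' @export
soft_threshold <- function(w, lam) {
  check_lambda(lam)
  sign(w) * pmax(abs(w) - lam, 0)
}

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("threshold `lam` must be a single value >= 0", call. = FALSE)
  }
  invisible(lam)
}

#' Universal (Donoho-Johnstone) threshold
#'
#' `sigma_hat * sqrt(2 * log(n_pixels))` with the noise level estimated
#' robustly from the finest-scale diagonal detail band as
#' `median(|coeffs|) / 0.6745` (the MAD estimator calibrated to the Gaussian).
#'
#' @param detail_coeffs finest-scale diagonal detail coefficients.
#' @param n_pixels number of pixels of the image being denoised.
#' @return The threshold value (a single number).
#' @export
universal_lambda <- function(detail_coeffs, n_pixels) {
  if (length(detail_coeffs) == 0L) {
    stop("empty detail band: cannot estimate noise level", call. = FALSE)
  }
  if (n_pixels < 1) stop("`n_pixels` must be positive", call. = FALSE)
  sigma_hat <- stats::median(abs(detail_coeffs)) / 0.6745
  sigma_hat * sqrt(2 * log(n_pixels))
}
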