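#' Mean square error between two images
#'
#' `MSE = (1/(M N)) * sum((f - f_hat)^2)` on the byte scale (both images are
#' converted to byte scale first, without quantization), matching the
#' convention that pairs with the byte-scale peak L = 255 in [psnr()].
#'
#' @param reference,test [gray_image()]s of identical dimensions.
#' @return A single number >= 0.
#' @export
mse <- function(reference, test) {
  assert_gray_image(reference); assert_gray_image(test)
  a <- convert_scale(reference, "byte")$pixels
  b <- convert_scale(test, "byte")$pixels
  if (!all(dim(a) == dim(b))) {
    stop("image dimensions differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  }
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `PSNR = 10 * log10(peak^2 / MSE)` with peak L = 255 (byte scale).
#' Identical images have MSE 0 and return `Inf`.
#'
#' @inheritParams mse
#' @param peak maximum gray value (default 255).
#' @return PSNR in dB (may be `Inf`).
#' @export
psnr <- function(reference, test, peak = 255) {
  e <- mse(reference, test)
  if (e == 0) return(Inf)
  10 * log10(peak^2 / e)
}

psnr_from_mse <- function(e, peak = 255) {
  ifelse(e == 0, Inf, 10 * log10(peak^2 / e))
}
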