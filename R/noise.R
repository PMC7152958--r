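#' Gaussian noise specification
#'
#' Describes the additive zero-mean white Gaussian noise used throughout the
#' simulations. Variances are on the unit intensity scale, so variance 0.01
#' corresponds to a standard deviation of about 25.5 gray levels on the byte
#' scale. The study sweep uses variances 0.01, 0.03, 0.05, 0.07, 0.09.
#'
#' @param variance noise variance on the unit scale, in (0, 1).
#' @param mean noise mean (0 in all experiments).
#' @param seed integer RNG seed; identical seeds give bit-identical noise.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(variance, mean = 0, seed = 1L) {
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0 ||
      variance >= 1) {
    stop("`variance` must be a single value in (0, 1)", call. = FALSE)
  }
  structure(list(mean = mean, variance = variance, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add seeded white Gaussian noise to a unit-scale image
#'
#' Adds i.i.d. N(mean, variance) noise per pixel and clamps the result to
#' \[0, 1\] so the noisy observation is a displayable image (the convention
#' adopted here; at the sweep's variances clamping affects only tails near
#' the range ends). The caller's RNG state is left untouched.
#'
#' @param img unit-scale [gray_image()].
#' @param spec a [noise_spec()].
#' @return A unit-scale `gray_image`, clamped.
#' @export
add_gaussian_noise <- function(img, spec) {
  assert_gray_image(img)
  if (!inherits(spec, "noise_spec")) {
    stop("`spec` must be a noise_spec", call. = FALSE)
  }
  if (img$scale != "unit") {
    stop("noise is defined on the unit scale; convert_scale(img, \"unit\") first",
         call. = FALSE)
  }
  px <- img$pixels
  noise <- with_seed(spec$seed, {
    matrix(stats::rnorm(length(px), mean = spec$mean,
                        sd = sqrt(spec$variance)),
           nrow(px), ncol(px))
  })
  gray_image(px + noise, scale = "unit", clamp = TRUE)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
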