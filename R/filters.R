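#' Wavelet shrinkage configuration
#'
#' @param wavelet_name orthogonal wavelet: one of `haar`, `db2`, `db4`,
#'   `sym4`, `sym8`. Default `sym4`.
#' @param levels decomposition depth (default 3).
#' @param threshold_rule `"universal"` (Donoho-Johnstone, with MAD noise
#'   estimate from the finest diagonal band, shared across levels) or
#'   `"fixed"`.
#' @param fixed_lambda threshold when `threshold_rule = "fixed"`.
#' @param mode `"hard"` or `"soft"`.
#' @param shrink_approximation_band also threshold the coarse approximation
#'   band (default `FALSE`, standard shrinkage practice).
#' @return A `wavelet_shrink_config` object.
#' @export
wavelet_shrink_config <- function(wavelet_name = "sym4", levels = 3L,
                                  threshold_rule = c("universal", "fixed"),
                                  fixed_lambda = 0, mode = c("hard", "soft"),
                                  shrink_approximation_band = FALSE) {
  threshold_rule <- match.arg(threshold_rule)
  mode <- match.arg(mode)
  if (fixed_lambda < 0) stop("`fixed_lambda` must be >= 0", call. = FALSE)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  structure(list(wavelet_name = wavelet_name, levels = as.integer(levels),
                 threshold_rule = threshold_rule, fixed_lambda = fixed_lambda,
                 mode = mode,
                 shrink_approximation_band = shrink_approximation_band),
            class = "wavelet_shrink_config")
}

#' Denoise an image by wavelet coefficient thresholding
#'
#' Multi-level orthogonal wavelet transform, thresholding of every detail
#' band with [hard_threshold()] or [soft_threshold()], inverse transform.
#' With the universal rule the threshold is `sigma_hat * sqrt(2 log(M N))`,
#' `sigma_hat` estimated by MAD from the finest diagonal band. A fixed
#' threshold of 0 returns the input up to transform round-off.
#'
#' @param img a [gray_image()] (any scale; the threshold adapts to the data).
#' @param config a [wavelet_shrink_config()].
#' @return A denoised `gray_image` on the same scale (not clamped).
#' @export
wavelet_denoise <- function(img, config = wavelet_shrink_config()) {
  assert_gray_image(img)
  if (!inherits(config, "wavelet_shrink_config")) {
    stop("`config` must be a wavelet_shrink_config", call. = FALSE)
  }
  x <- img$pixels
  if (any(!is.finite(x))) stop("image has non-finite pixels", call. = FALSE)
  co <- dwt2(x, config$wavelet_name, config$levels)
  lam <- switch(config$threshold_rule,
    fixed = config$fixed_lambda,
    universal = universal_lambda(co$detail[[1]]$HH, length(x))
  )
  shrink <- if (config$mode == "hard") hard_threshold else soft_threshold
  for (j in seq_len(config$levels)) {
    for (b in c("LH", "HL", "HH")) {
      co$detail[[j]][[b]] <- shrink(co$detail[[j]][[b]], lam)
    }
  }
  if (isTRUE(config$shrink_approximation_band)) {
    co$approx <- shrink(co$approx, lam)
  }
  gray_image(idwt2(co), scale = img$scale, clamp = FALSE)
}

#' Wiener filter configuration
#'
#' @param mode `"local"` (pixelwise-adaptive local statistics, the default
#'   used in the denoising pipeline) or `"frequency"` (the classical power-
#'   spectral form).
#' @param window odd window edge for local mode (default 3).
#' @param noise_variance noise variance on the image's intensity scale, or
#'   `"estimate"` (local mode only) to use the mean of all local variances.
#' @param blur_kernel optional point-spread function for frequency mode;
#'   `NULL` means no blur (identity H).
#' @return A `wiener_config` object.
#' @export
wiener_config <- function(mode = c("local", "frequency"), window = 3L,
                          noise_variance = "estimate", blur_kernel = NULL) {
  mode <- match.arg(mode)
  if (!identical(noise_variance, "estimate")) {
    if (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
        noise_variance < 0) {
      stop("`noise_variance` must be >= 0 or \"estimate\"", call. = FALSE)
    }
  } else if (mode == "frequency") {
    stop("frequency mode needs a numeric `noise_variance`", call. = FALSE)
  }
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(mode = mode, window = as.integer(window),
                 noise_variance = noise_variance, blur_kernel = blur_kernel),
            class = "wiener_config")
}

#' Pixelwise-adaptive (local-statistics) Wiener filter
#'
#' For each pixel, with mean `mu` and variance `s2` over a mirror-padded
#' `window x window` neighbourhood, the output is
#' `mu + max(s2 - v, 0) / max(s2, v) * (x - mu)`, where `v` is the noise
#' variance (or the mean of all local variances when estimated). Flat
#' regions are replaced by their local mean; high-variance regions pass
#' almost unchanged, which preserves edges.
#'
#' @param img a [gray_image()].
#' @param config a [wiener_config()] with `mode = "local"`.
#' @return A filtered `gray_image` on the same scale (not clamped).
#' @export
wiener_local <- function(img, config = wiener_config()) {
  assert_gray_image(img)
  stopifnot(inherits(config, "wiener_config"))
  if (config$mode != "local") stop("config$mode must be \"local\"", call. = FALSE)
  x <- img$pixels
  w <- config$window
  if (w >= min(dim(x))) {
    stop("window (", w, ") must be smaller than the image extent ",
         min(dim(x)), call. = FALSE)
  }
  v <- config$noise_variance
  # zero assumed noise: the gain is identically 1, so the filter is the
  # identity; return the input untouched rather than accumulate round-off
  if (is.numeric(v) && v == 0) return(img)
  # anchor the data before computing moments: constant windows then have
  # exactly zero mean and variance, free of box-filter round-off
  anchor <- x[1L, 1L]
  xc <- x - anchor
  muc <- box_mean(xc, w)
  mu <- anchor + muc
  s2 <- pmax(box_mean(xc * xc, w) - muc * muc, 0)
  if (identical(v, "estimate")) v <- mean(s2)
  gain <- pmax(s2 - v, 0) / pmax(s2, v)
  gain[s2 == 0 & v == 0] <- 1  # degenerate 0/0: pass through
  out <- mu + gain * (x - mu)
  # a zero-variance window is constant, where mu = x analytically; use x to
  # avoid box-filter round-off (makes constant images exact fixed points)
  flat <- s2 == 0
  out[flat] <- x[flat]
  gray_image(out, scale = img$scale, clamp = FALSE)
}

# mean over a w x w mirror-padded sliding window (separable box filter)
box_mean <- function(x, w) {
  h <- (w - 1L) %/% 2L
  acc <- matrix(0, nrow(x), ncol(x))
  for (t in -h:h) acc <- acc + x[sym_index(nrow(x), t), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (t in -h:h) out <- out + acc[, sym_index(ncol(x), t), drop = FALSE]
  out / (w * w)
}

#' Frequency-domain Wiener filter
#'
#' The classical spectral form `H* / (|H|^2 + S_eta / S_f)` applied in the
#' discrete Fourier domain. The noise power spectrum is flat,
#' `S_eta = variance * M * N`; the signal spectrum is estimated from the
#' observation as `max(|G|^2 - S_eta, delta)` with a small positive floor
#' `delta` guarding the division. With zero noise variance and no blur the
#' filter is the identity.
#'
#' @param img a [gray_image()].
#' @param config a [wiener_config()] with `mode = "frequency"` and numeric
#'   `noise_variance`.
#' @param delta positive floor for the signal-spectrum estimate.
#' @return A filtered `gray_image` on the same scale (not clamped).
#' @export
wiener_frequency <- function(img, config, delta = 1e-12) {
  assert_gray_image(img)
  stopifnot(inherits(config, "wiener_config"))
  if (config$mode != "frequency") {
    stop("config$mode must be \"frequency\"", call. = FALSE)
  }
  x <- img$pixels
  M <- nrow(x); N <- ncol(x)
  G <- stats::fft(x)
  S_eta <- config$noise_variance * M * N
  H <- matrix(1 + 0i, M, N)
  if (!is.null(config$blur_kernel)) {
    k <- config$blur_kernel
    if (nrow(k) > M || ncol(k) > N) {
      stop("blur kernel larger than the image", call. = FALSE)
    }
    kp <- matrix(0, M, N)
    kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
    # center the kernel at the origin (circular shift)
    kp <- kp[sym_shift(M, (nrow(k) - 1L) %/% 2L), , drop = FALSE]
    kp <- kp[, sym_shift(N, (ncol(k) - 1L) %/% 2L), drop = FALSE]
    H <- stats::fft(kp)
  }
  S_f <- pmax(Mod(G)^2 - S_eta, delta)
  W <- Conj(H) / (Mod(H)^2 + S_eta / S_f)
  out <- Re(stats::fft(W * G, inverse = TRUE)) / (M * N)
  gray_image(out, scale = img$scale, clamp = FALSE)
}

# circular shift indices so row (h+1) moves to row 1
sym_shift <- function(n, h) ((seq_len(n) - 1L + h) %% n) + 1L

#' Robust noise-level estimate from the finest wavelet band
#'
#' `median(|HH1|) / 0.6745`, the MAD estimator applied to the finest
#' diagonal detail band of a single-level sym4 transform — the classical
#' robust sigma estimate, insensitive to image structure.
#'
#' @param img a [gray_image()].
#' @return Estimated noise standard deviation on the image's scale.
#' @export
estimate_noise_sigma <- function(img) {
  assert_gray_image(img)
  co <- dwt2(img$pixels, "sym4", 1L)
  stats::median(abs(co$detail[[1]]$HH)) / 0.6745
}
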