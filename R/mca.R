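#' MCA solver configuration
#'
#' Controls the block-coordinate iterative-thresholding solver that splits an
#' image into cartoon and texture components, with the residual defined as
#' what remains. The threshold descends linearly from a data-driven maximum
#' (second-largest coefficient magnitude across both dictionaries at start,
#' so the very first iteration already transfers at least one atom) down to
#' `lambda_min` over `n_iterations`.
#'
#' @param n_iterations number of outer iterations (default 100).
#' @param lambda_min final threshold (default 0: run the schedule to its
#'   end). Setting a positive value, e.g. `3 * sigma`, leaves coefficients
#'   below it to the residual part.
#' @param schedule descent schedule; `"linear"` is the only option.
#' @param lambda_max_rule how the initial threshold is set;
#'   `"from_coefficients"` is the only option.
#' @param cartoon_dictionary,texture_dictionary dictionaries built with
#'   [build_cartoon_dictionary()] / [build_texture_dictionary()], or `NULL`
#'   for the defaults (starlet, 4 levels; block DCT 16 with 50% overlap).
#' @return An `mca_config` object.
#' @export
mca_config <- function(n_iterations = 100L, lambda_min = 0,
                       schedule = "linear",
                       lambda_max_rule = "from_coefficients",
                       cartoon_dictionary = NULL,
                       texture_dictionary = NULL) {
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (lambda_min < 0) stop("`lambda_min` must be >= 0", call. = FALSE)
  schedule <- match.arg(schedule, "linear")
  lambda_max_rule <- match.arg(lambda_max_rule, "from_coefficients")
  if (is.null(cartoon_dictionary)) cartoon_dictionary <- build_cartoon_dictionary()
  if (is.null(texture_dictionary)) texture_dictionary <- build_texture_dictionary()
  stopifnot(inherits(cartoon_dictionary, "mca_dictionary"),
            inherits(texture_dictionary, "mca_dictionary"))
  structure(list(n_iterations = as.integer(n_iterations),
                 lambda_min = lambda_min, schedule = schedule,
                 lambda_max_rule = lambda_max_rule,
                 cartoon_dictionary = cartoon_dictionary,
                 texture_dictionary = texture_dictionary),
            class = "mca_config")
}

#' Decompose an image into cartoon, texture, and residual parts
#'
#' Morphological component analysis by block-coordinate relaxation: at each
#' iteration, each component in turn is re-estimated by hard-thresholding
#' the analysis coefficients of its marginal residual (the input minus the
#' other component) at the current threshold and resynthesizing. The coarse
#' approximation band of the cartoon dictionary is never thresholded — the
#' low-frequency content always belongs to the cartoon part. After the
#' schedule finishes, `residual = input - cartoon - texture`, so the three
#' parts sum to the input exactly (to floating-point round-off) for every
#' input and configuration. Parts are not clamped: only their sum is an
#' image.
#'
#' @param img a [gray_image()] (decomposition is scale-agnostic; the
#'   denoising pipeline uses the unit scale).
#' @param config an [mca_config()].
#' @param track_residual_energy record `sum(residual^2)` after every
#'   iteration in the `residual_energy` field (costs one subtraction per
#'   iteration; default `FALSE`).
#' @return An `mca_decomposition`: list with `cartoon`, `texture`,
#'   `residual` (gray_images on the input scale, unclamped),
#'   `iterations_run`, `final_threshold`, and optionally `residual_energy`.
#' @export
mca_decompose <- function(img, config = mca_config(),
                          track_residual_energy = FALSE) {
  assert_gray_image(img)
  stopifnot(inherits(config, "mca_config"))
  s <- img$pixels
  if (any(!is.finite(s))) stop("image has non-finite pixels", call. = FALSE)
  dc <- config$cartoon_dictionary
  dt <- config$texture_dictionary
  n_it <- config$n_iterations

  cs0 <- dc$analyze(s)
  ct0 <- dt$analyze(s)
  mags <- c(abs(unlist(cs0$detail, use.names = FALSE)),
            abs(unlist(ct0$detail, use.names = FALSE)))
  lambda_max <- sort(mags, decreasing = TRUE)[2L]
  lam_seq <- if (n_it == 1L) config$lambda_min else {
    seq(lambda_max, config$lambda_min, length.out = n_it)
  }

  cartoon <- matrix(0, nrow(s), ncol(s))
  texture <- matrix(0, nrow(s), ncol(s))
  energy <- if (track_residual_energy) numeric(n_it) else NULL

  for (t in seq_len(n_it)) {
    lam <- lam_seq[t]
    # cartoon update: threshold detail bands only, keep the coarse band
    cs <- dc$analyze(s - texture)
    cs$detail <- lapply(cs$detail, hard_threshold, lam = lam)
    cartoon <- dc$synthesize(cs)
    # texture update: all block-DCT coefficients are thresholdable
    ct <- dt$analyze(s - cartoon)
    ct$detail <- lapply(ct$detail, hard_threshold, lam = lam)
    texture <- dt$synthesize(ct)
    if (track_residual_energy) {
      energy[t] <- sum((s - cartoon - texture)^2)
    }
  }

  structure(list(
    cartoon  = gray_image(cartoon, img$scale, clamp = FALSE),
    texture  = gray_image(texture, img$scale, clamp = FALSE),
    residual = gray_image(s - cartoon - texture, img$scale, clamp = FALSE),
    iterations_run = n_it,
    final_threshold = lam_seq[length(lam_seq)],
    residual_energy = energy,
    input_scale = img$scale
  ), class = "mca_decomposition")
}

#' @export
print.mca_decomposition <- function(x, ...) {
  cat(sprintf(paste0(
    "<mca_decomposition> %d x %d (%s scale), %d iterations, ",
    "final threshold %.4g\n"),
    nrow(x$cartoon$pixels), ncol(x$cartoon$pixels), x$input_scale,
    x$iterations_run, x$final_threshold))
  for (p in c("cartoon", "texture", "residual")) {
    cat(sprintf("  %-8s energy %.4g\n", p, sum(x[[p]]$pixels^2)))
  }
  invisible(x)
}

#' Tidy summary of an MCA decomposition
#'
#' One row per part with its energy and share of the total input energy.
#'
#' @param x an `mca_decomposition`.
#' @param ... unused.
#' @return A tibble with columns `part`, `energy`, `energy_fraction`,
#'   `min`, `max`.
#' @export
tidy.mca_decomposition <- function(x, ...) {
  input <- x$cartoon$pixels + x$texture$pixels + x$residual$pixels
  tot <- sum(input^2)
  parts <- c("cartoon", "texture", "residual")
  tibble::tibble(
    part = parts,
    energy = vapply(parts, function(p) sum(x[[p]]$pixels^2), numeric(1)),
    energy_fraction = energy / tot,
    min = vapply(parts, function(p) min(x[[p]]$pixels), numeric(1)),
    max = vapply(parts, function(p) max(x[[p]]$pixels), numeric(1))
  )
}

#' Fraction of a ground-truth layer's energy captured by a part
#'
#' The projection coefficient `<part, truth> / <truth, truth>`: 1 when the
#' part reproduces the layer exactly, 0 when it is orthogonal to it.
#'
#' @param part a [gray_image()] or matrix (a decomposition part).
#' @param truth the known ground-truth layer.
#' @return A single number.
#' @export
energy_capture <- function(part, truth) {
  p <- as_pixel_matrix(part)
  g <- as_pixel_matrix(truth)
  stopifnot(all(dim(p) == dim(g)))
  sum(p * g) / sum(g * g)
}
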