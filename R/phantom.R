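#' Phantom specification
#'
#' Synthetic test images with known morphology layers, standing in for real
#' axial brain MR slices (which cannot be redistributed): a piecewise-smooth
#' "cartoon" layer built from nested smoothed ellipses (a Shepp-Logan-like
#' construction) plus an oscillatory "texture" layer of windowed oriented
#' cosine gratings. Because the two layers are stored separately, tests can
#' measure how much of each layer a decomposition part captures.
#'
#' @param size square image edge in pixels (default 256).
#' @param n_ellipses number of ellipses (>= 1); the first is the large
#'   head-like outline, the rest are seeded interior structures.
#' @param ellipse_intensity_range intensity interval for interior ellipse
#'   increments (absolute value; signs alternate via the seed).
#' @param texture_frequency grating frequency in cycles per image width
#'   (default 32, i.e. an 8-pixel period at size 256).
#' @param texture_amplitude grating amplitude on the unit scale
#'   (default 0.12).
#' @param texture_region `"mask"` (grating only inside the head outline,
#'   the default) or `"global"`.
#' @param smooth_sigma Gaussian edge-softening sigma in pixels (default 1.5;
#'   0 for crisp indicator edges).
#' @param seed integer seed controlling ellipse geometry and grating
#'   orientation.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size = 256L, n_ellipses = 4L,
                         ellipse_intensity_range = c(0.08, 0.18),
                         texture_frequency = 32, texture_amplitude = 0.12,
                         texture_region = c("mask", "global"),
                         smooth_sigma = 1.5, seed = 1L) {
  texture_region <- match.arg(texture_region)
  if (size < 32L) stop("`size` must be >= 32", call. = FALSE)
  if (n_ellipses < 1L) stop("`n_ellipses` must be >= 1", call. = FALSE)
  if (smooth_sigma < 0) stop("`smooth_sigma` must be >= 0", call. = FALSE)
  if (texture_amplitude < 0) {
    stop("`texture_amplitude` must be >= 0", call. = FALSE)
  }
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 ellipse_intensity_range = ellipse_intensity_range,
                 texture_frequency = texture_frequency,
                 texture_amplitude = texture_amplitude,
                 texture_region = texture_region,
                 smooth_sigma = smooth_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom with known cartoon and texture ground truth
#'
#' The clean image is `clamp(cartoon_truth + texture_truth)`; amplitudes are
#' validated so that clamping destroys less than 5% of the texture layer's
#' energy (otherwise the ground-truth layers would no longer describe the
#' clean image).
#'
#' @param spec a [phantom_spec()].
#' @return A list with unit-scale [gray_image()]s `clean`, `cartoon_truth`,
#'   `texture_truth` (the truth layers unclamped) and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  with_seed(spec$seed, {
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    cx <- (xs - (n + 1) / 2) / n
    cy <- (ys - (n + 1) / 2) / n

    ellipse <- function(x0, y0, a, b, theta) {
      ct <- cos(theta); st <- sin(theta)
      u <- (cx - x0) * ct + (cy - y0) * st
      v <- -(cx - x0) * st + (cy - y0) * ct
      (u / a)^2 + (v / b)^2 <= 1
    }

    head_mask <- ellipse(0, 0, 0.38, 0.45, 0)
    cartoon <- 0.55 * head_mask
    if (spec$n_ellipses > 1L) {
      lo <- spec$ellipse_intensity_range[1]
      hi <- spec$ellipse_intensity_range[2]
      for (k in seq_len(spec$n_ellipses - 1L)) {
        amp <- stats::runif(1, lo, hi) * sample(c(-1, 1), 1)
        x0 <- stats::runif(1, -0.18, 0.18)
        y0 <- stats::runif(1, -0.22, 0.22)
        a <- stats::runif(1, 0.05, 0.16)
        b <- stats::runif(1, 0.05, 0.16)
        th <- stats::runif(1, 0, pi)
        cartoon <- cartoon + amp * ellipse(x0, y0, a, b, th)
      }
    }
    cartoon <- pmin(pmax(cartoon, 0), 0.85)
    if (spec$smooth_sigma > 0) {
      cartoon <- gaussian_smooth(cartoon, spec$smooth_sigma)
    }

    theta <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    freq <- spec$texture_frequency / n  # cycles per pixel
    grating <- cos(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys) + phase)
    win <- if (spec$texture_region == "mask") {
      m <- ellipse(0, 0, 0.30, 0.36, 0) * 1.0
      gaussian_smooth(m, max(spec$smooth_sigma, 2))
    } else {
      matrix(1, n, n)
    }
    texture <- spec$texture_amplitude * win * grating
  })

  clean_raw <- cartoon + texture
  clean <- pmin(pmax(clean_raw, 0), 1)
  lost <- sum((clean - clean_raw)^2)
  tex_energy <- sum(texture^2)
  if (tex_energy > 0 && lost > 0.05 * tex_energy) {
    stop("clamping destroys ", sprintf("%.1f%%", 100 * lost / tex_energy),
         " of the texture layer's energy; reduce `texture_amplitude` or ",
         "the cartoon intensities", call. = FALSE)
  }
  list(clean = gray_image(clean, "unit"),
       cartoon_truth = gray_image(cartoon, "unit", clamp = FALSE),
       texture_truth = gray_image(texture, "unit", clamp = FALSE),
       spec = spec)
}

# separable Gaussian smoothing with mirror boundary
gaussian_smooth <- function(x, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(x), ncol(x))
  for (t in -h:h) {
    out <- out + k[t + h + 1L] * x[sym_index(nrow(x), t), , drop = FALSE]
  }
  res <- matrix(0, nrow(x), ncol(x))
  for (t in -h:h) {
    res <- res + k[t + h + 1L] * out[, sym_index(ncol(x), t), drop = FALSE]
  }
  res
}

#' The three default study phantoms
#'
#' Three phantoms with differing geometry seeds, ellipse counts, and grating
#' frequency/orientation, mirroring a study design with three distinct
#' images.
#'
#' @param size image edge (default 256).
#' @return Named list of three [make_phantom()] results
#'   (`phantom1`..`phantom3`).
#' @export
default_phantoms <- function(size = 256L) {
  specs <- list(
    phantom1 = phantom_spec(size = size, n_ellipses = 4L, seed = 101L,
                            texture_frequency = size / 8),
    phantom2 = phantom_spec(size = size, n_ellipses = 6L, seed = 202L,
                            texture_frequency = size / 6,
                            texture_amplitude = 0.10),
    phantom3 = phantom_spec(size = size, n_ellipses = 3L, seed = 303L,
                            texture_frequency = size / 10,
                            texture_amplitude = 0.14)
  )
  lapply(specs, make_phantom)
}

#' Write a phantom test suite to disk
#'
#' Writes the three default phantoms plus seeded noisy versions at each
#' requested variance, as 8-bit PNGs with `.rds` sidecars holding the exact
#' float pixel values, and a JSON manifest listing every file with its
#' provenance (spec, variance, seed).
#'
#' @param dir output directory (created if missing).
#' @param seeds integer seeds (default 1).
#' @param variances noise variances
#'   (default `c(0.01, 0.03, 0.05, 0.07, 0.09)`).
#' @param size phantom edge (default 256).
#' @return Path of the manifest JSON, invisibly.
#' @export
make_test_suite <- function(dir, seeds = 1L,
                            variances = c(0.01, 0.03, 0.05, 0.07, 0.09),
                            size = 256L) {
  if (length(seeds) == 0L || length(variances) == 0L) {
    stop("`seeds` and `variances` must be non-empty", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output dir: ", dir, call. = FALSE)
  phantoms <- default_phantoms(size)
  entries <- list()
  for (id in names(phantoms)) {
    ph <- phantoms[[id]]
    base <- file.path(dir, id)
    write_image(ph$clean, paste0(base, "_clean.png"))
    saveRDS(ph$clean$pixels, paste0(base, "_clean.rds"))
    entries[[length(entries) + 1L]] <- list(
      file = paste0(id, "_clean.png"), image_id = id, kind = "clean",
      size = size, spec_seed = ph$spec$seed)
    for (v in variances) for (sd_ in as.integer(seeds)) {
      noisy <- add_gaussian_noise(ph$clean, noise_spec(v, seed = sd_))
      nm <- sprintf("%s_noisy_v%s_s%d", id, format(v), sd_)
      write_image(noisy, file.path(dir, paste0(nm, ".png")))
      saveRDS(noisy$pixels, file.path(dir, paste0(nm, ".rds")))
      entries[[length(entries) + 1L]] <- list(
        file = paste0(nm, ".png"), image_id = id, kind = "noisy",
        variance = v, seed = sd_, size = size)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
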