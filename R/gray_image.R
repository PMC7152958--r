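#' Grayscale image container
#'
#' A `gray_image` is a real-valued intensity matrix (`M` rows by `N` columns)
#' tagged with its intensity scale: `"unit"` (values in \[0, 1\]) or `"byte"`
#' (values in \[0, 255\]). Pixels are stored as doubles throughout; nothing is
#' quantized to 8 bits until the image is written to disk, which avoids
#' double-quantization bias when computing MSE against a float-valued
#' reference.
#'
#' Transform stages require a minimal spatial extent, so images smaller than
#' 8 x 8 are rejected.
#'
#' @param pixels numeric matrix of intensities.
#' @param scale `"unit"` or `"byte"`.
#' @param clamp clamp values into the scale's range (default `TRUE`). Internal
#'   stages that legitimately produce out-of-range values (e.g. individual MCA
#'   parts) pass `clamp = FALSE`.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, scale = c("unit", "byte"), clamp = TRUE) {
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8 x 8 (got ", nrow(pixels), " x ",
         ncol(pixels), ")", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (clamp) {
    hi <- if (scale == "unit") 1 else 255
    pixels[pixels < 0] <- 0
    pixels[pixels > hi] <- hi
  }
  structure(list(pixels = pixels, scale = scale),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, scale=%s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x, arg = deparse(substitute(x))) {
  if (!is_gray_image(x)) {
    stop("`", arg, "` must be a gray_image (see gray_image())", call. = FALSE)
  }
  invisible(x)
}

#' Convert an image between unit and byte intensity scales
#'
#' Linear rescaling by a factor of 255 (or 1/255). No rounding occurs, so a
#' unit -> byte -> unit round trip reproduces the input to machine precision.
#' Both scales are needed because noise variances are specified on the unit
#' scale while PSNR uses the byte-scale peak L = 255.
#'
#' @param img a [gray_image()].
#' @param target `"unit"` or `"byte"`.
#' @return A `gray_image` on the target scale.
#' @export
convert_scale <- function(img, target = c("unit", "byte")) {
  assert_gray_image(img)
  target <- match.arg(target)
  if (img$scale == target) return(img)
  f <- if (target == "byte") 255 else 1 / 255
  gray_image(img$pixels * f, scale = target, clamp = FALSE)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Color input is collapsed to luminance with Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B); gray pixels are unaffected by the choice of
#' weights. 16-bit input is rescaled linearly so that full scale maps to 255.
#' The result is always on the byte scale.
#'
#' @param path path to a `.png`, `.tif`, or `.tiff` file.
#' @return A byte-scale [gray_image()].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for ", path,
         " (PNG or TIFF expected)", call. = FALSE)
  )
  if (length(arr) == 0L) {
    stop("zero-sized image: ", path, call. = FALSE)
  }
  # readers return values in [0,1] regardless of bit depth
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(arr * 255, scale = "byte")
}

#' Write an image as 8-bit grayscale PNG or TIFF
#'
#' The only place where quantization happens: intensities are clamped to the
#' scale range and rounded to 8 bits by the writer.
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.png`, `.tif`, or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray_image(img)
  u <- convert_scale(img, "unit")$pixels
  u[u < 0] <- 0
  u[u > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(u, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(u, where = path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Rescale an arbitrary real-valued part for display
#'
#' MCA parts may individually leave the displayable range; this affine map
#' sends their min/max to 0/1 for visual inspection only.
#'
#' @param pixels numeric matrix.
#' @return A unit-scale [gray_image()].
#' @export
display_rescale <- function(pixels) {
  if (is_gray_image(pixels)) pixels <- pixels$pixels
  rng <- range(pixels)
  if (diff(rng) == 0) {
    return(gray_image(matrix(0.5, nrow(pixels), ncol(pixels)), "unit"))
  }
  gray_image((pixels - rng[1]) / diff(rng), "unit")
}
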