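test_that("gray_image validates dimensions and clamps to its scale", {
  expect_error(gray_image(matrix(0, 4, 4)), "8 x 8")
  expect_error(gray_image("not a matrix"), "numeric matrix")
  img <- gray_image(matrix(c(-0.5, 0.2, 1.7, rep(0.5, 61)), 8, 8), "unit")
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  raw <- gray_image(matrix(c(-0.5, 1.7, rep(0.5, 62)), 8, 8), "unit",
                    clamp = FALSE)
  expect_equal(min(raw$pixels), -0.5)
})

test_that("scale conversion is linear, invertible, and exact at anchors", {
  img <- gray_image(matrix(c(0, 0.5, 1, rep(0.25, 61)), 8, 8), "unit")
  byte <- convert_scale(img, "byte")
  expect_equal(byte$pixels[1, 1], 0)
  expect_equal(byte$pixels[2, 1], 127.5)
  expect_equal(byte$pixels[3, 1], 255)
  back <- convert_scale(byte, "unit")
  expect_lt(max(abs(back$pixels - img$pixels)), 1e-12)
  # round trip on arbitrary values, no quantization in memory
  r <- rand_image(16, seed = 7)
  rt <- convert_scale(convert_scale(r, "byte"), "unit")
  expect_lt(max(abs(rt$pixels - r$pixels)), 1e-12)
})

test_that("PNG and TIFF round trips preserve 8-bit gray content", {
  px <- matrix(128 / 255, 16, 16)
  p <- file.path(tempdir(), "flat.png")
  png::writePNG(px, p)
  img <- load_image(p)
  expect_equal(img$scale, "byte")
  expect_true(all(img$pixels == 128))

  # RGB gray pixels collapse to the same gray under luminance weights
  rgb <- array(200 / 255, c(12, 12, 3))
  p2 <- file.path(tempdir(), "gray_rgb.png")
  png::writePNG(rgb, p2)
  img2 <- load_image(p2)
  expect_true(all(abs(img2$pixels - 200) < 1e-9))

  # 16-bit TIFF full scale maps to 255
  p3 <- file.path(tempdir(), "full16.tif")
  tiff::writeTIFF(matrix(1, 64, 64), p3, bits.per.sample = 16L)
  img3 <- load_image(p3)
  expect_true(all(img3$pixels == 255))

  # write path quantizes to 8 bits and reads back identically
  r <- rand_image(16, seed = 3)
  p4 <- file.path(tempdir(), "rt.png")
  write_image(r, p4)
  rt <- load_image(p4)
  expect_lt(max(abs(rt$pixels / 255 - r$pixels)), 1 / 255 + 1e-9)

  expect_error(load_image(file.path(tempdir(), "missing.png")), "not found")
  bmp <- file.path(tempdir(), "flat.bmp")
  writeLines("not an image", bmp)
  expect_error(load_image(bmp), "format")
})

test_that("seeded Gaussian noise is reproducible and has the right moments", {
  img <- gray_image(matrix(0.5, 256, 256), "unit")
  spec <- noise_spec(0.01, seed = 11)
  n1 <- add_gaussian_noise(img, spec)
  n2 <- add_gaussian_noise(img, spec)
  expect_identical(n1$pixels, n2$pixels)

  delta <- n1$pixels - img$pixels
  # at 0.5 intensity and sd 0.1, clamping is negligible
  expect_lt(abs(mean(delta)), 3 * 0.1 / sqrt(length(delta)))
  expect_lt(abs(stats::var(as.vector(delta)) - 0.01), 0.1 * 0.01)

  # a different seed gives a different realization
  n3 <- add_gaussian_noise(img, noise_spec(0.01, seed = 12))
  expect_false(identical(n1$pixels, n3$pixels))

  # output is clamped to the unit range even at high variance
  hi <- add_gaussian_noise(img, noise_spec(0.5, seed = 1))
  expect_gte(min(hi$pixels), 0)
  expect_lte(max(hi$pixels), 1)
})

test_that("noise model rejects invalid specs and scales", {
  expect_error(noise_spec(0), "variance")
  expect_error(noise_spec(-0.1), "variance")
  expect_error(noise_spec(1), "variance")
  byte_img <- gray_image(matrix(128, 8, 8), "byte")
  expect_error(add_gaussian_noise(byte_img, noise_spec(0.01)), "unit scale")
})

test_that("noise addition does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(add_gaussian_noise(gray_image(matrix(0.5, 8, 8), "unit"),
                               noise_spec(0.01, seed = 5)))
  b <- runif(1)
  expect_identical(a, b)
})
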