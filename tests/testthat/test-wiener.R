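test_that("local Wiener matches the brute-force sliding-window oracle", {
  set.seed(31)
  for (rep in 1:3) {
    x <- matrix(runif(16 * 16), 16, 16)
    img <- gray_image(x, "unit")
    for (w in c(3L, 5L)) {
      got <- wiener_local(img, wiener_config(window = w,
                                             noise_variance = 0.01))
      want <- wiener_local_bruteforce(x, w, 0.01)
      expect_lt(max(abs(got$pixels - want)), 1e-12)
      got_e <- wiener_local(img, wiener_config(window = w))
      want_e <- wiener_local_bruteforce(x, w, "estimate")
      expect_lt(max(abs(got_e$pixels - want_e)), 1e-12)
    }
  }
})

test_that("local Wiener is exactly the identity in its degenerate cases", {
  const <- gray_image(matrix(0.37, 16, 16), "unit")
  out <- wiener_local(const, wiener_config(noise_variance = 0.05))
  expect_identical(out$pixels, const$pixels)

  r <- rand_image(16, seed = 8)
  out0 <- wiener_local(r, wiener_config(noise_variance = 0))
  expect_identical(out0$pixels, r$pixels)
})

test_that("local Wiener never amplifies deviation from the local mean", {
  r <- rand_image(24, seed = 9)
  w <- 5L
  out <- wiener_local(r, wiener_config(window = w, noise_variance = 0.02))
  mu <- mcadenoise:::box_mean(r$pixels, w)
  expect_true(all(abs(out$pixels - mu) <= abs(r$pixels - mu) + 1e-14))
})

test_that("the hand-derived 5x5 single-spike case matches", {
  # image must be at least 8x8; embed the spike so the 3x3 windows around it
  # see the same neighborhood as the textbook 5x5 case
  x <- matrix(0, 8, 8)
  x[4, 4] <- 1
  v <- 0.01
  out <- wiener_local(gray_image(x, "unit", clamp = FALSE),
                      wiener_config(window = 3L, noise_variance = v))
  mu <- 1 / 9
  s2 <- 1 / 9 - (1 / 9)^2  # E[x^2] - mu^2 over the 3x3 window
  expect_equal(s2, 8 / 81)
  want_center <- mu + (s2 - v) / s2 * (1 - mu)
  expect_equal(out$pixels[4, 4], want_center, tolerance = 1e-12)
})

test_that("frequency Wiener reduces to identity without noise or blur", {
  r <- rand_image(32, seed = 10)
  out <- wiener_frequency(r, wiener_config(mode = "frequency",
                                           noise_variance = 0))
  expect_lt(max(abs(out$pixels - r$pixels)), 1e-8)
})

test_that("frequency Wiener preserves the mean and kills huge noise", {
  const <- gray_image(matrix(0.6, 32, 32), "unit")
  out <- wiener_frequency(const, wiener_config(mode = "frequency",
                                               noise_variance = 0.05))
  expect_lt(max(abs(out$pixels - 0.6)) / 0.6, 0.01)

  r <- rand_image(32, seed = 11)
  out2 <- wiener_frequency(r, wiener_config(mode = "frequency",
                                            noise_variance = 1e9))
  expect_lt(sum(out2$pixels^2) / sum(r$pixels^2), 0.05)
})

test_that("wiener config validation catches bad parameters", {
  expect_error(wiener_config(window = 4L), "odd")
  expect_error(wiener_config(window = 1L), "odd")
  expect_error(wiener_config(noise_variance = -1), ">= 0")
  expect_error(wiener_config(mode = "frequency"), "numeric")
  r <- rand_image(16, seed = 1)
  expect_error(wiener_local(r, wiener_config(window = 17L)), "smaller")
  big_kernel <- matrix(1 / 400, 20, 20)
  cfg <- wiener_config(mode = "frequency", noise_variance = 0.01,
                       blur_kernel = big_kernel)
  expect_error(wiener_frequency(r, cfg), "larger than the image")
})
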