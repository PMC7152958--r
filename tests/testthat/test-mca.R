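# the fast config used where the test only exercises structural properties
fast_mca <- function(...) {
  mca_config(n_iterations = 10L,
             cartoon_dictionary = build_cartoon_dictionary(3),
             texture_dictionary = build_texture_dictionary(8, 1 / 2), ...)
}

test_that("cartoon + texture + residual equals the input exactly", {
  set.seed(51)
  inputs <- c(
    lapply(1:3, function(i) rand_image(32, seed = i)),
    list(small_phantom(64)$clean)
  )
  for (img in inputs) {
    dec <- mca_decompose(img, fast_mca())
    total <- dec$cartoon$pixels + dec$texture$pixels + dec$residual$pixels
    expect_lt(max(abs(total - img$pixels)), 1e-10)
  }
})

test_that("the zero image is a fixed point", {
  dec <- mca_decompose(zero_image(32), fast_mca())
  expect_true(all(dec$cartoon$pixels == 0))
  expect_true(all(dec$texture$pixels == 0))
  expect_true(all(dec$residual$pixels == 0))
})

test_that("decomposition is deterministic and records its run metadata", {
  img <- small_phantom(64)$clean
  a <- mca_decompose(img, fast_mca(lambda_min = 0.01))
  b <- mca_decompose(img, fast_mca(lambda_min = 0.01))
  expect_identical(a$cartoon$pixels, b$cartoon$pixels)
  expect_identical(a$texture$pixels, b$texture$pixels)
  expect_equal(a$iterations_run, 10L)
  expect_equal(a$final_threshold, 0.01)
})

test_that("each morphology lands in its matching part on the phantom", {
  ph <- make_phantom(phantom_spec())  # the default 256-pixel phantom
  dec <- mca_decompose(ph$clean, mca_config())
  expect_gte(energy_capture(dec$texture, ph$texture_truth), 0.70)
  expect_gte(energy_capture(dec$cartoon, ph$cartoon_truth), 0.70)
})

test_that("dictionary roles are symmetric: each pure layer goes to its part", {
  ph <- small_phantom(128)
  # pure oscillatory input: the texture part takes nearly all the energy
  tex_only <- gray_image(ph$texture_truth$pixels, "unit", clamp = FALSE)
  dec_t <- mca_decompose(tex_only, mca_config())
  frac_t <- sum(dec_t$texture$pixels^2) /
    (sum(dec_t$cartoon$pixels^2) + sum(dec_t$texture$pixels^2) + 1e-300)
  expect_gte(frac_t, 0.7)
  # pure piecewise-smooth input: the cartoon part takes nearly all of it
  dec_c <- mca_decompose(ph$cartoon_truth, mca_config())
  frac_c <- sum(dec_c$cartoon$pixels^2) /
    (sum(dec_c$cartoon$pixels^2) + sum(dec_c$texture$pixels^2) + 1e-300)
  expect_gte(frac_c, 0.7)
})

test_that("residual energy is non-increasing at schedule checkpoints", {
  ph <- small_phantom(64)
  dec <- mca_decompose(ph$clean, mca_config(n_iterations = 20L),
                       track_residual_energy = TRUE)
  e <- dec$residual_energy
  n <- length(e)
  expect_lte(e[n %/% 2], e[1] + 1e-12)
  expect_lte(e[n], e[n %/% 2] + 1e-12)
})

test_that("mca_decompose validates input and config", {
  expect_error(mca_config(n_iterations = 0), ">= 1")
  expect_error(mca_config(lambda_min = -1), ">= 0")
  bad <- rand_image(32, seed = 1)
  bad$pixels[5, 5] <- Inf
  expect_error(mca_decompose(bad, fast_mca()), "non-finite")
})

test_that("tidy() summarises part energies consistently", {
  dec <- mca_decompose(small_phantom(64)$clean, fast_mca())
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$part, c("cartoon", "texture", "residual"))
  expect_true(all(td$energy >= 0))
})
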