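test_that("benchmark produces the expected record and average cardinality", {
  ph <- small_phantom(64)
  bm <- run_benchmark(list(p1 = ph$clean),
                      variances = c(0.01, 0.03, 0.05, 0.07, 0.09),
                      methods = c("wiener", "hard", "soft", "noisy"),
                      seeds = 1L)
  expect_equal(nrow(bm$records), 1 * 5 * 4 * 1)
  expect_equal(nrow(bm$averages), 5 * 4)
  expect_equal(nrow(bm$max_rows), 5)
})

test_that("records satisfy the PSNR/MSE cross-field identity", {
  ph <- small_phantom(64)
  bm <- run_benchmark(list(p1 = ph$clean), variances = 0.05,
                      methods = c("wiener", "hard", "soft"), seeds = 1:2)
  with_mse <- bm$records[bm$records$mse > 0, ]
  expect_equal(with_mse$psnr, 10 * log10(255^2 / with_mse$mse),
               tolerance = 1e-12)
})

test_that("max rows and averages satisfy their defining identities", {
  ph1 <- small_phantom(64, seed = 101)
  ph2 <- small_phantom(64, seed = 202)
  bm <- run_benchmark(list(a = ph1$clean, b = ph2$clean),
                      variances = c(0.03, 0.07),
                      methods = c("wiener", "hard", "soft"), seeds = 1L)
  rec <- bm$records
  for (i in seq_len(nrow(bm$max_rows))) {
    row <- bm$max_rows[i, ]
    cell <- rec[rec$image_id == row$image_id & rec$variance == row$variance &
                  rec$seed == row$seed, ]
    expect_equal(row$psnr, max(cell$psnr))
  }
  for (i in seq_len(nrow(bm$averages))) {
    row <- bm$averages[i, ]
    cell <- rec[rec$variance == row$variance &
                  rec$method_label == row$method_label, ]
    expect_equal(row$psnr, mean(cell$psnr), tolerance = 1e-12)
    expect_equal(row$mse, mean(cell$mse), tolerance = 1e-12)
  }
})

test_that("every method is scored against the same noisy realization", {
  ph <- small_phantom(64)
  bm <- run_benchmark(list(p1 = ph$clean), variances = 0.05,
                      methods = c("noisy", "noisy"), seeds = 7L)
  expect_equal(bm$records$mse[1], bm$records$mse[2])
})

test_that("benchmark CSV export is byte-identical across reruns", {
  ph <- small_phantom(64)
  f1 <- file.path(tempdir(), "bm1.csv")
  f2 <- file.path(tempdir(), "bm2.csv")
  for (f in c(f1, f2)) {
    bm <- run_benchmark(list(p1 = ph$clean), variances = c(0.01, 0.09),
                        methods = c("wiener", "soft"), seeds = 3L)
    write_benchmark_csv(bm, f)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("benchmark rejects empty inputs", {
  ph <- small_phantom(64)
  expect_error(run_benchmark(list(), variances = 0.05), "non-empty")
  expect_error(run_benchmark(list(ph$clean), variances = numeric(0)),
               "non-empty")
  expect_error(run_benchmark(list(ph$clean), methods = character(0)),
               "non-empty")
})

test_that("tidiers and autoplot work on benchmark results", {
  ph <- small_phantom(64)
  bm <- run_benchmark(list(p1 = ph$clean), variances = 0.05,
                      methods = c("wiener", "soft"), seeds = 1L)
  expect_s3_class(tidy(bm), "tbl_df")
  gl <- glance(bm)
  expect_equal(nrow(gl), 2)
  expect_true(all(c("mean_mse", "mean_psnr") %in% names(gl)))
  p <- autoplot(bm)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(bm, metric = "mse")
  expect_s3_class(p2, "ggplot")
})
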