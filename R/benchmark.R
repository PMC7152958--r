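#' Noise-variance sweep benchmark
#'
#' For every combination of clean image, noise variance, and seed, one noisy
#' realization is drawn and *every* requested method is scored against that
#' same realization, so that method differences are not confounded with
#' noise draws. Methods may be standalone denoisers (`"wiener"`, `"hard"`,
#' `"soft"`, `"noisy"` for the unfiltered baseline) or three-letter hybrid
#' assignment labels (`"WHS"`, ...).
#'
#' @param clean_images named list of clean unit-scale [gray_image()]s
#'   (names become `image_id`; unnamed lists get `image1`, `image2`, ...).
#' @param variances noise variances on the unit scale
#'   (default `c(0.01, 0.03, 0.05, 0.07, 0.09)`).
#' @param methods character vector of method labels.
#' @param seeds integer seeds (default 1).
#' @param mca_cfg [mca_config()] used by hybrid assignments, or `NULL` for
#'   the noise-adaptive pipeline default (see [denoise_hybrid()]).
#' @param filter_configs per-method configs (see
#'   [default_filter_configs()]); the same configs are used for standalone
#'   methods and for every hybrid assignment.
#' @return A `benchmark_result`: list with `records` (tibble, one row per
#'   image x variance x seed x method with `mse` and `psnr`), `averages`
#'   (per variance x method means over images and seeds), and `max_rows`
#'   (per image x variance, the best PSNR over the requested methods).
#' @export
run_benchmark <- function(clean_images,
                          variances = c(0.01, 0.03, 0.05, 0.07, 0.09),
                          methods = c("wiener", "hard", "soft", "WHS"),
                          seeds = 1L,
                          mca_cfg = NULL,
                          filter_configs = default_filter_configs()) {
  if (length(clean_images) == 0L || length(variances) == 0L ||
      length(methods) == 0L || length(seeds) == 0L) {
    stop("`clean_images`, `variances`, `methods`, and `seeds` must all be ",
         "non-empty", call. = FALSE)
  }
  if (is_gray_image(clean_images)) clean_images <- list(clean_images)
  if (is.null(names(clean_images))) {
    names(clean_images) <- paste0("image", seq_along(clean_images))
  }
  grid <- expand.grid(image_id = names(clean_images), variance = variances,
                      seed = as.integer(seeds), stringsAsFactors = FALSE)
  standalone <- c("wiener", "hard", "soft", "noisy")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    id <- grid$image_id[i]; v <- grid$variance[i]; sd_ <- grid$seed[i]
    clean <- clean_images[[id]]
    noisy <- add_gaussian_noise(clean, noise_spec(v, seed = sd_))
    # one decomposition per noisy realization, shared by all assignments
    dec <- NULL
    if (any(!methods %in% standalone)) {
      cfg <- mca_cfg
      if (is.null(cfg)) {
        cfg <- mca_config(lambda_min = 3 * estimate_noise_sigma(noisy))
      }
      dec <- mca_decompose(noisy, cfg)
    }
    lapply(methods, function(m) {
      out <- if (m %in% standalone) {
        o <- apply_method(noisy, m, filter_configs)
        gray_image(o$pixels, scale = o$scale, clamp = TRUE)
      } else {
        filter_decomposition(dec, method_assignment(m), filter_configs)
      }
      e <- mse(clean, out)
      tibble::tibble(image_id = id, variance = v, seed = sd_,
                     method_label = m, mse = e, psnr = psnr_from_mse(e))
    })
  })
  records <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  averages <- records |>
    dplyr::group_by(.data$variance, .data$method_label) |>
    dplyr::summarise(mse = mean(.data$mse), psnr = mean(.data$psnr),
                     .groups = "drop")
  max_rows <- records |>
    dplyr::group_by(.data$image_id, .data$variance, .data$seed) |>
    dplyr::summarise(psnr = max(.data$psnr),
                     best_method = .data$method_label[which.max(.data$psnr)],
                     .groups = "drop")
  structure(list(records = records, averages = averages, max_rows = max_rows,
                 methods = methods),
            class = "benchmark_result")
}

#' Six-permutation ablation over filter-to-part assignments
#'
#' Runs [run_benchmark()] with the six assignments SHW, SWH, HSW, HWS, WSH,
#' WHS. The per-image, per-variance decomposition is shared implicitly
#' through the common noisy realization; the `max_rows` element gives the
#' best assignment per cell, and `averages` the per-variance means across
#' images.
#'
#' @inheritParams run_benchmark
#' @return A `benchmark_result` over the six assignments.
#' @export
run_ablation <- function(clean_images,
                         variances = c(0.01, 0.03, 0.05, 0.07, 0.09),
                         seeds = 1L,
                         mca_cfg = NULL,
                         filter_configs = default_filter_configs()) {
  labels <- vapply(enumerate_assignments(), `[[`, character(1), "label")
  run_benchmark(clean_images, variances, labels, seeds, mca_cfg,
                filter_configs)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", nrow(x$records), " records (",
      length(unique(x$records$image_id)), " images x ",
      length(unique(x$records$variance)), " variances x ",
      length(unique(x$records$seed)), " seeds x ",
      length(x$methods), " methods)\n", sep = "")
  print(x$averages, n = 20)
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) x$records

#' @export
glance.benchmark_result <- function(x, ...) {
  x$records |>
    dplyr::group_by(.data$method_label) |>
    dplyr::summarise(mean_mse = mean(.data$mse), mean_psnr = mean(.data$psnr),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Line plot of mean PSNR (or MSE) against noise variance
#'
#' One line per method — the shape of the study's summary figures.
#'
#' @param object a `benchmark_result`.
#' @param metric `"psnr"` or `"mse"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, metric = c("psnr", "mse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$averages,
                  ggplot2::aes(x = .data$variance, y = .data[[metric]],
                               colour = .data$method_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "noise variance (unit scale)",
                  y = if (metric == "psnr") "mean PSNR (dB)" else "mean MSE",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Write benchmark records to CSV
#'
#' Deterministic output: identical seeds give byte-identical files.
#'
#' @param x a `benchmark_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(x, path) {
  stopifnot(inherits(x, "benchmark_result"))
  utils::write.csv(as.data.frame(x$records), path, row.names = FALSE)
  invisible(path)
}

#' Display an image or decomposition parts with ggplot2
#'
#' @param img a [gray_image()], or an `mca_decomposition` (whose three parts
#'   are shown side by side, each affine-rescaled for display).
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  if (inherits(img, "mca_decomposition")) {
    df <- dplyr::bind_rows(lapply(c("cartoon", "texture", "residual"),
      function(p) {
        d <- image_df(display_rescale(img[[p]]))
        d$part <- factor(p, levels = c("cartoon", "texture", "residual"))
        d
      }))
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                           fill = .data$value)) +
      ggplot2::facet_wrap(~part)
  } else {
    assert_gray_image(img)
    gg <- ggplot2::ggplot(image_df(img),
                          ggplot2::aes(.data$col, .data$row,
                                       fill = .data$value))
  }
  gg +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

image_df <- function(img) {
  px <- img$pixels
  tibble::tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    value = as.vector(px)
  )
}
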