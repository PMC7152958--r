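#' Transform dictionaries for morphological component analysis
#'
#' A dictionary is a perfect-reconstruction analysis/synthesis pair tuned to
#' one image morphology. The cartoon dictionary is the shift-invariant
#' starlet wavelet (B3-spline a-trous scheme), which codes piecewise-smooth
#' structure sparsely; the texture dictionary is an overlapping windowed
#' block DCT, which codes locally periodic oscillation sparsely. Both are
#' exact inverses of each other by construction, for any image size.
#'
#' `analyze()` returns a `coefficient_set`: a list with `detail` (the
#' thresholdable coefficient arrays) and `approx` (a coarse band that MCA
#' never thresholds; `NULL` for the texture dictionary) plus the geometry
#' needed for exact synthesis.
#'
#' @name dictionaries
NULL

new_dictionary <- function(name, kind, analyze, synthesize, params) {
  structure(list(name = name, kind = kind, analyze = analyze,
                 synthesize = synthesize, params = params),
            class = "mca_dictionary")
}

#' @export
print.mca_dictionary <- function(x, ...) {
  cat(sprintf("<mca_dictionary> %s (kind=%s)\n", x$name, x$kind))
  invisible(x)
}

#' Build the cartoon (starlet) dictionary
#'
#' Undecimated isotropic B3-spline wavelet with `levels` detail scales and a
#' coarse approximation band. Mirror boundary handling; exact reconstruction
#' by summation of bands.
#'
#' @param levels number of detail scales (>= 1).
#' @param wavelet_name kernel identifier; only `"b3spline"` is provided.
#' @return An `mca_dictionary` with `kind = "cartoon"`.
#' @export
build_cartoon_dictionary <- function(levels = 4L, wavelet_name = "b3spline") {
  if (!identical(wavelet_name, "b3spline")) {
    stop("unknown cartoon kernel '", wavelet_name,
         "'; only \"b3spline\" is available", call. = FALSE)
  }
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  levels <- as.integer(levels)
  analyze <- function(x) {
    x <- as_pixel_matrix(x)
    maxlev <- max_starlet_levels(nrow(x), ncol(x))
    if (levels > maxlev) {
      stop("levels=", levels, " too deep for a ", nrow(x), " x ", ncol(x),
           " image (max feasible depth ", maxlev, ")", call. = FALSE)
    }
    st <- starlet_analyze(x, levels)
    structure(list(detail = st$details, approx = st$approx,
                   dictionary = "starlet", dims = dim(x), levels = levels),
              class = "coefficient_set")
  }
  synthesize <- function(cs) {
    starlet_synthesize(list(details = cs$detail, approx = cs$approx))
  }
  new_dictionary("starlet", "cartoon", analyze, synthesize,
                 list(levels = levels, wavelet_name = wavelet_name))
}

#' Build the texture (windowed block DCT) dictionary
#'
#' Overlapping blocks of an orthonormal 2-D DCT-II, weighted by a separable
#' sine window so overlapped synthesis windows sum smoothly; synthesis
#' overlap-adds the windowed inverse blocks and divides by the accumulated
#' window-squared weight map, which makes reconstruction exact everywhere.
#' With `overlap = 0` the window is flat and blocks tile without overlap.
#'
#' @param block_size block edge in pixels: 8, 16 or 32.
#' @param overlap fraction of block overlap: 0 or 1/2.
#' @return An `mca_dictionary` with `kind = "texture"`.
#' @export
build_texture_dictionary <- function(block_size = 16L, overlap = 1 / 2) {
  if (!block_size %in% c(8L, 16L, 32L)) {
    stop("`block_size` must be 8, 16 or 32", call. = FALSE)
  }
  if (!overlap %in% c(0, 1 / 2)) {
    stop("`overlap` must be 0 or 1/2", call. = FALSE)
  }
  B <- as.integer(block_size)
  hop <- as.integer(B * (1 - overlap))
  w1 <- if (overlap == 0) rep(1, B) else sin(pi * (seq_len(B) - 0.5) / B)
  w2d <- outer(w1, w1)
  D <- dct_matrix(B)
  geom_cache <- new.env(parent = emptyenv())

  geometry <- function(n, m) {
    key <- paste(n, m)
    g <- geom_cache[[key]]
    if (!is.null(g)) return(g)
    g <- dct_geometry(n, m, B, hop, w2d)
    geom_cache[[key]] <- g
    g
  }

  analyze <- function(x) {
    x <- as_pixel_matrix(x)
    if (nrow(x) < B || ncol(x) < B) {
      stop("image (", nrow(x), " x ", ncol(x),
           ") smaller than one ", B, " x ", B, " block", call. = FALSE)
    }
    g <- geometry(nrow(x), ncol(x))
    xp <- x[g$row_map, , drop = FALSE][, g$col_map, drop = FALSE]
    blocks <- array(xp[g$idx], c(B, B, g$nb)) * c(w2d)
    co <- block_tensor(blocks, D)
    structure(list(detail = list(co), approx = NULL,
                   dictionary = "block_dct", dims = dim(x), block = B),
              class = "coefficient_set")
  }

  synthesize <- function(cs) {
    g <- geometry(cs$dims[1], cs$dims[2])
    blocks <- block_tensor(cs$detail[[1]], t(D)) * c(w2d)
    out <- matrix(0, g$P_r, g$P_c)
    for (s in seq_along(g$sub_idx)) {
      ii <- g$sub_idx[[s]]
      out[g$idx[ii]] <- out[g$idx[ii]] + blocks[ii]
    }
    out <- out / g$weight
    out[g$crop_r, g$crop_c, drop = FALSE]
  }

  new_dictionary("block_dct", "texture", analyze, synthesize,
                 list(block_size = B, overlap = overlap, hop = hop))
}

as_pixel_matrix <- function(x) {
  if (is_gray_image(x)) x$pixels else x
}

# orthonormal DCT-II matrix
dct_matrix <- function(B) {
  k <- 0:(B - 1L)
  i <- 0:(B - 1L)
  D <- sqrt(2 / B) * cos(pi * outer(k, 2 * i + 1) / (2 * B))
  D[1, ] <- sqrt(1 / B)
  D
}

# apply matrix D along the first two axes of a (B, B, nb) array
block_tensor <- function(arr, D) {
  B <- dim(arr)[1]; nb <- dim(arr)[3]
  y <- array(D %*% matrix(arr, B, B * nb), c(B, B, nb))
  y <- aperm(y, c(2, 1, 3))
  y <- array(D %*% matrix(y, B, B * nb), c(B, B, nb))
  aperm(y, c(2, 1, 3))
}

# block layout for an n x m image: mirror padding of B on each side (rounded
# up so the hop lattice tiles exactly), block linear indices into the padded
# matrix, collision-free subgrids for overlap-add, and the window weight map
dct_geometry <- function(n, m, B, hop, w2d) {
  pad_dim <- function(n) {
    P <- n + 2L * B
    r <- (P - B) %% hop
    if (r != 0L) P <- P + (hop - r)
    P
  }
  P_r <- pad_dim(n); P_c <- pad_dim(m)
  row_map <- sym_pos(0:(P_r - 1L) - B, n)
  col_map <- sym_pos(0:(P_c - 1L) - B, m)
  org_r <- seq.int(1L, P_r - B + 1L, hop)
  org_c <- seq.int(1L, P_c - B + 1L, hop)
  nb <- length(org_r) * length(org_c)
  block_rc <- expand.grid(r = org_r, c = org_c)
  within_block <- outer(0:(B - 1L), (0:(B - 1L)) * P_r, `+`)
  origin_lin <- (block_rc$r) + (block_rc$c - 1L) * P_r
  idx <- outer(c(within_block), origin_lin, `+`)  # (B*B) x nb
  f <- B %/% hop
  sub <- (((block_rc$r - 1L) %/% hop) %% f) + f * (((block_rc$c - 1L) %/% hop) %% f)
  sub_idx <- lapply(sort(unique(sub)), function(s) {
    which(rep(sub == s, each = B * B))
  })
  weight <- matrix(0, P_r, P_c)
  w2sq <- c(w2d)^2
  for (s in seq_along(sub_idx)) {
    ii <- sub_idx[[s]]
    weight[c(idx)[ii]] <- weight[c(idx)[ii]] + rep_len(w2sq, length(ii))
  }
  list(P_r = P_r, P_c = P_c, row_map = row_map, col_map = col_map,
       idx = c(idx), nb = nb, sub_idx = sub_idx, weight = weight,
       crop_r = (B + 1L):(B + n), crop_c = (B + 1L):(B + m))
}
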