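# Fixtures are generated in code; nothing binary ships with the package.

rand_image <- function(n = 32, m = n, seed = 1, scale = "unit") {
  set.seed(seed)
  lo <- 0
  hi <- if (scale == "unit") 1 else 255
  gray_image(matrix(runif(n * m, lo, hi), n, m), scale = scale)
}

zero_image <- function(n = 32, scale = "unit") {
  gray_image(matrix(0, n, n), scale = scale)
}

# small phantom shared by several tests
small_phantom <- function(size = 128, seed = 101) {
  make_phantom(phantom_spec(size = size, seed = seed,
                            texture_frequency = size / 8))
}

# brute-force sliding-window local Wiener: the independent oracle, written
# as literal double loops over pixels and window members
wiener_local_bruteforce <- function(x, window, v = "estimate") {
  h <- (window - 1) %/% 2
  n <- nrow(x); m <- ncol(x)
  reflect <- function(i, n) {
    # half-sample symmetric: ...2,1 | 1..n | n,n-1...
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  mu <- matrix(0, n, m); s2 <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- numeric(0)
    for (di in -h:h) for (dj in -h:h) {
      vals <- c(vals, x[reflect(i + di, n), reflect(j + dj, m)])
    }
    mu[i, j] <- mean(vals)
    s2[i, j] <- mean(vals^2) - mean(vals)^2
  }
  if (identical(v, "estimate")) v <- mean(s2)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    g <- max(s2[i, j] - v, 0) / max(s2[i, j], v)
    if (s2[i, j] == 0 && v == 0) g <- 1
    out[i, j] <- mu[i, j] + g * (x[i, j] - mu[i, j])
  }
  out
}

# brute-force double-loop MSE on byte-scale matrices
mse_bruteforce <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    acc <- acc + (a[i, j] - b[i, j])^2
  }
  acc / (nrow(a) * ncol(a))
}
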