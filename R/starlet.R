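# Shift-invariant (undecimated) isotropic wavelet transform -- the "starlet"
# built on the B3-spline kernel (1,4,6,4,1)/16. At level j the kernel taps are
# spread 2^(j-1) samples apart (the a-trous scheme). Details are successive
# differences of smoothings, so synthesis is plain summation and perfect
# reconstruction is exact by construction. Boundaries use half-sample
# symmetric (mirror) extension.

B3_KERNEL <- c(1, 4, 6, 4, 1) / 16

# half-sample symmetric reflection of indices 1..n shifted by `off`
# (off may be any integer; reflection has period 2n)
sym_index <- function(n, off) {
  i <- seq_len(n) + off
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# separable 5-tap smoothing with taps spaced `d` apart, mirror boundary
b3_smooth <- function(x, d) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (t in -2:2) {
    out <- out + B3_KERNEL[t + 3L] * x[sym_index(n, t * d), , drop = FALSE]
  }
  res <- matrix(0, n, m)
  for (t in -2:2) {
    res <- res + B3_KERNEL[t + 3L] * out[, sym_index(m, t * d), drop = FALSE]
  }
  res
}

starlet_analyze <- function(x, levels) {
  stopifnot(levels >= 1)
  details <- vector("list", levels)
  c_prev <- x
  for (j in seq_len(levels)) {
    c_next <- b3_smooth(c_prev, 2L^(j - 1L))
    details[[j]] <- c_prev - c_next
    c_prev <- c_next
  }
  list(details = details, approx = c_prev, levels = levels)
}

starlet_synthesize <- function(coeffs) {
  Reduce(`+`, coeffs$details, coeffs$approx)
}

max_starlet_levels <- function(n, m) {
  # level j needs the dilated kernel half-width 2^j to stay within half the
  # image extent, so the mirror extension remains meaningful
  max(1L, floor(log2(min(n, m) / 2)))
}
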