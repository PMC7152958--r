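# Decimated orthogonal 2-D wavelet transform with half-sample symmetric
# boundary extension. Coefficient vectors keep every window that touches the
# signal (length about (n + L)/2 per band per axis), so reconstruction is
# exact for any signal length: the two-channel orthonormal filter bank is
# perfectly reconstructing on the mirror-extended signal, and all windows
# needed to resynthesize the original samples are retained.

WAVELET_FILTERS <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2  = c(-0.12940952255126037, 0.22414386804201339,
           0.83651630373780794, 0.48296291314453416),
  db4  = c(-0.010597401785069032, 0.032883011666885197,
           0.030841381835560764, -0.18703481171909309,
           -0.027983769416859854, 0.63088076792985892,
           0.71484657055291567, 0.23037781330889651),
  sym4 = c(-0.075765714789273325, -0.02963552764599851,
           0.49761866763201545, 0.80373875180591614,
           0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054,
           -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037,
           -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609)
)

wavelet_filters <- function(name) {
  lo <- WAVELET_FILTERS[[name]]
  if (is.null(lo)) {
    stop("unknown wavelet '", name, "'; available: ",
         paste(names(WAVELET_FILTERS), collapse = ", "), call. = FALSE)
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)  # quadrature mirror filter
  list(lo = lo, hi = hi, L = L)
}

# symmetric-extension row indices for 0-based positions p (any integers)
sym_pos <- function(p, n) {
  p0 <- p %% (2L * n)
  ifelse(p0 < n, p0 + 1L, 2L * n - p0)
}

# one analysis step along columns of X; returns approx/detail matrices
dwt_step_cols <- function(X, f) {
  n <- nrow(X); L <- f$L
  kmin <- ceiling((1 - L) / 2)
  kmax <- floor((n - 1) / 2)
  ks <- kmin:kmax
  a <- matrix(0, length(ks), ncol(X))
  d <- matrix(0, length(ks), ncol(X))
  for (m in 0:(L - 1L)) {
    rows <- sym_pos(2L * ks + m, n)
    xm <- X[rows, , drop = FALSE]
    a <- a + f$lo[m + 1L] * xm
    d <- d + f$hi[m + 1L] * xm
  }
  list(a = a, d = d, n = n, kmin = kmin)
}

# inverse of dwt_step_cols: reconstructs the original n rows exactly
idwt_step_cols <- function(a, d, f, n, kmin) {
  L <- f$L
  nk <- nrow(a)
  pad <- L
  ncols <- ncol(a)
  ua <- matrix(0, 2L * nk + 2L * pad, ncols)
  ud <- ua
  up_rows <- 2L * (seq_len(nk) - 1L) + pad + 1L
  ua[up_rows, ] <- a
  ud[up_rows, ] <- d
  out <- matrix(0, n, ncols)
  ts <- 0:(n - 1L)
  for (m in 0:(L - 1L)) {
    rows <- ts - m - 2L * kmin + pad + 1L
    out <- out + f$lo[m + 1L] * ua[rows, , drop = FALSE] +
                 f$hi[m + 1L] * ud[rows, , drop = FALSE]
  }
  out
}

# single-level 2-D step: columns then rows
dwt2_step <- function(X, f) {
  cstep <- dwt_step_cols(X, f)
  ra <- dwt_step_cols(t(cstep$a), f)
  rd <- dwt_step_cols(t(cstep$d), f)
  list(LL = t(ra$a), LH = t(ra$d),  # LH: horizontal detail (row-axis highpass)
       HL = t(rd$a), HH = t(rd$d),
       n = cstep$n, m = ra$n, kmin_r = cstep$kmin, kmin_c = ra$kmin)
}

idwt2_step <- function(bands, f) {
  a <- t(idwt_step_cols(t(bands$LL), t(bands$LH), f = f,
                        n = bands$m, kmin = bands$kmin_c))
  d <- t(idwt_step_cols(t(bands$HL), t(bands$HH), f = f,
                        n = bands$m, kmin = bands$kmin_c))
  idwt_step_cols(a, d, f, n = bands$n, kmin = bands$kmin_r)
}

max_dwt_levels <- function(n, m, L) {
  lev <- 0L
  sz <- min(n, m)
  while (sz >= max(2L * L, 8L)) {
    lev <- lev + 1L
    sz <- floor((sz + L - 1L) / 2L)
    if (lev >= 12L) break
  }
  max(lev, 0L)
}

# multi-level decomposition; returns list of per-level detail bands plus the
# coarsest approximation and the geometry needed for exact inversion
dwt2 <- function(X, wavelet = "sym4", levels = 3L) {
  f <- wavelet_filters(wavelet)
  maxlev <- max_dwt_levels(nrow(X), ncol(X), f$L)
  if (levels < 1L || levels > maxlev) {
    stop("levels=", levels, " infeasible for a ", nrow(X), " x ", ncol(X),
         " image with the ", wavelet, " filter (max ", maxlev, ")",
         call. = FALSE)
  }
  detail <- vector("list", levels)
  cur <- X
  for (j in seq_len(levels)) {
    st <- dwt2_step(cur, f)
    detail[[j]] <- st[c("LH", "HL", "HH", "n", "m", "kmin_r", "kmin_c")]
    cur <- st$LL
  }
  list(detail = detail, approx = cur, wavelet = wavelet, levels = levels)
}

idwt2 <- function(coeffs) {
  f <- wavelet_filters(coeffs$wavelet)
  cur <- coeffs$approx
  for (j in rev(seq_len(coeffs$levels))) {
    b <- coeffs$detail[[j]]
    b$LL <- cur
    cur <- idwt2_step(b, f)
  }
  cur
}
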