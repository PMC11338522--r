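# Shared numeric primitives: separable Gaussian convolution, bilinear
# sampling, half-up rounding. Conventions here are load-bearing for the
# estimators (half-open binning, 4-sigma kernel truncation) and are asserted
# by the test suite against brute-force oracles.

# Half-up rounding: round(0.5) -> 1. R's round() uses banker's rounding,
# which would make bound-punctum counts depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Normalized 1D Gaussian kernel truncated at 4 sigma (in pixels).
# Truncation keeps < 0.01% of the mass outside the support; normalization
# makes the discrete kernel exactly mass-conserving.
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- ceiling(4 * sigma_px)
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# 1D convolution of the columns of `mat` with kernel `k` (odd length),
# zero-padded: vectorized shift-and-add.
conv_cols <- function(mat, k) {
  n <- length(k)
  if (n == 1L) return(mat * k)
  r <- (n - 1L) / 2L
  nr <- nrow(mat)
  pad <- matrix(0, r, ncol(mat))
  padded <- rbind(pad, mat, pad)
  out <- matrix(0, nr, ncol(mat))
  for (j in seq_len(n)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

# Separable isotropic Gaussian blur with 4-sigma truncation.
blur_gaussian <- function(mat, sigma_px) {
  k <- gauss_kernel(sigma_px)
  t(conv_cols(t(conv_cols(mat, k)), k))
}

# Bilinear interpolation of `mat` at continuous pixel-center coordinates
# (row, col), where integer coordinates address pixel centers. Points must
# lie within [0.5, n + 0.5] in both axes (the physical image extent);
# sampling positions are clamped to the center grid at the half-pixel rim.
bilinear <- function(mat, row, col) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (any(row < 0.5 - 1e-9) || any(row > nr + 0.5 + 1e-9) ||
      any(col < 0.5 - 1e-9) || any(col > nc + 0.5 + 1e-9)) {
    abort("Sampling position outside the image extent.",
          class = "axc_error_geometry")
  }
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  v00 <- mat[cbind(r0, c0)];     v10 <- mat[cbind(r0 + 1, c0)]
  v01 <- mat[cbind(r0, c0 + 1)]; v11 <- mat[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Resample a polyline (matrix/data frame with columns x, y) at `n` evenly
# spaced arc-length positions from 0 to the total length. The grid is
# symmetric, so resampling the reversed polyline yields the reversed points.
resample_polyline <- function(xy, step, n = NULL) {
  xy <- as.matrix(xy)
  seg <- diff(xy)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) abort("Consecutive polyline vertices must be distinct.",
                           class = "axc_error_parameter")
  total <- sum(len)
  if (is.null(n)) n <- max(2L, floor(total / step) + 1L)
  s <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(seg))
  frac <- (s - cum[idx]) / len[idx]
  pts <- xy[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tan <- seg[idx, , drop = FALSE] / len[idx]
  list(points = pts, tangents = tan, arc = s, total_length = total)
}

# Piecewise-constant weighted sampling of x positions over [0, L]:
# `breaks` are interval edges (length m + 1), `weights` relative densities
# per interval (length m).
sample_piecewise <- function(n, breaks, weights) {
  stopifnot(length(breaks) == length(weights) + 1L)
  widths <- diff(breaks)
  mass <- widths * weights
  if (n == 0L || sum(mass) <= 0) return(numeric(0))
  comp <- sample.int(length(weights), n, replace = TRUE, prob = mass)
  breaks[comp] + runif(n) * widths[comp]
}

# Polynomial rolling hash of a canonical JSON rendering; fingerprints a
# configuration so a report can be tied back to the exact parameters that
# produced it. Two words of different moduli to keep collisions unlikely.
hash_config <- function(x) {
  txt <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                       null = "null", force = TRUE))
  bytes <- utf8ToInt(txt)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483629
    h2 <- (h2 * 137 + b) %% 2147483587
  }
  sprintf("%08x%08x", h1, h2)
}
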