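# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Value of the neighbour in direction (dr, dc) at every pixel, with
# replicated (zero-flux) borders.
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m)
  w <- ncol(m)
  ri <- clamp(seq_len(h) + dr, 1L, h)
  ci <- clamp(seq_len(w) + dc, 1L, w)
  m[ri, ci, drop = FALSE]
}

# 2D correlation with an odd-sized kernel and replicated borders:
# out(x) = sum_d k(d) * m(x + d).
correlate_replicate <- function(m, kernel) {
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  rh <- (kh - 1L) %/% 2L
  rw <- (kw - 1L) %/% 2L
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -rh:rh) {
    for (dc in -rw:rw) {
      wgt <- kernel[dr + rh + 1L, dc + rw + 1L]
      if (wgt != 0) acc <- acc + wgt * shift_replicate(m, dr, dc)
    }
  }
  acc
}

# Bilinear sampling of a field at continuous (row, col) points.
# Pixel (i, j) (1-based) has its centre at (i - 0.5, j - 0.5), i.e. the
# 0-based pixel (r, c) is centred at (r + 0.5, c + 0.5).
bilinear_sample <- function(field, pts) {
  h <- nrow(field)
  w <- ncol(field)
  fy <- clamp(pts[, 1L] + 0.5, 1, h)
  fx <- clamp(pts[, 2L] + 0.5, 1, w)
  y0 <- pmin(floor(fy), h - 1L)
  x0 <- pmin(floor(fx), w - 1L)
  dy <- fy - y0
  dx <- fx - x0
  f00 <- field[cbind(y0, x0)]
  f10 <- field[cbind(y0 + 1L, x0)]
  f01 <- field[cbind(y0, x0 + 1L)]
  f11 <- field[cbind(y0 + 1L, x0 + 1L)]
  (1 - dy) * (1 - dx) * f00 + dy * (1 - dx) * f10 +
    (1 - dy) * dx * f01 + dy * dx * f11
}

# Gaussian blur that accepts and returns a plain matrix; sd = 0 is identity.
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  out <- EBImage::gblur(m, sigma = sd)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(matrix(0.5, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}
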