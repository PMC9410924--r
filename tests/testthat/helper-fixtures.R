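# Shared fixtures and independent oracles, built in code.

disc_mask <- function(shape, center, radius) {
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h) - 0.5, h, w)
  cc <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  matrix(as.integer((rr - center[1])^2 + (cc - center[2])^2 <= radius^2),
         h, w)
}

circle_contour <- function(center, radius, n = 100) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  as_contour(cbind(center[1] + radius * sin(th),
                   center[2] + radius * cos(th)))
}

# Per-pixel scalar PCNN simulation: explicit loops over pixels and kernel
# offsets, the module's reference oracle. Replicated borders.
pcnn_brute_force <- function(image, params, n_iter) {
  h <- nrow(image); w <- ncol(image)
  f <- l <- u <- matrix(0, h, w)
  theta <- matrix(params$theta0, h, w)
  y <- matrix(0L, h, w)
  km <- params$kernel_m; kw <- params$kernel_w
  rk <- (nrow(km) - 1) / 2
  fired <- vector("list", n_iter)
  corr <- function(yprev, kern, i, j) {
    s <- 0
    for (di in -rk:rk) for (dj in -rk:rk) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      s <- s + kern[di + rk + 1, dj + rk + 1] * yprev[ii, jj]
    }
    s
  }
  for (a in seq_len(n_iter)) {
    yprev <- y
    fn <- f; ln <- l; un <- u; yn <- y; thn <- theta
    for (i in seq_len(h)) for (j in seq_len(w)) {
      fn[i, j] <- params$decay_f * f[i, j] + image[i, j] +
        params$vf * corr(yprev, km, i, j)
      ln[i, j] <- params$decay_l * l[i, j] +
        params$vl * corr(yprev, kw, i, j)
      un[i, j] <- fn[i, j] * (1 + params$beta * ln[i, j])
      yn[i, j] <- as.integer(un[i, j] > theta[i, j])
      thn[i, j] <- params$decay_theta * theta[i, j] +
        params$vtheta * yn[i, j]
    }
    f <- fn; l <- ln; u <- un; y <- yn; theta <- thn
    fired[[a]] <- y
  }
  fired
}

# Two-level test phantom used by several segmentation tests.
quiet_phantom <- function(sigma, seed = 1, shape = c(96, 96)) {
  generate_phantom(shape = shape, sigma = sigma, seed = seed)
}
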