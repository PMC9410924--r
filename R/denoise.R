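#' Parameters for Perona-Malik anisotropic diffusion
#'
#' @param k Edge-stopping threshold in gradient-magnitude units, or
#'   `"auto"` to use the 90th percentile of the non-zero 4-neighbour
#'   gradient magnitudes of the (possibly log-transformed) input.
#' @param lambda Explicit-scheme step weight, in `(0, 0.25]` for stability
#'   of the 4-neighbour discretisation.
#' @param iterations Number of diffusion steps, >= 0.
#' @param variant Diffusion coefficient: `"rational"` `1/(1+(g/k)^2)` or
#'   `"exponential"` `exp(-(g/k)^2)`.
#' @param log_domain Diffuse `ln(I + offset)` instead of `I` (homomorphic
#'   treatment of multiplicative speckle); default `TRUE`.
#' @param offset Log-transform stabiliser, see [log_transform()].
#' @return A list of class `diffusion_params`.
#' @export
diffusion_params <- function(k = "auto", lambda = 0.2, iterations = 30L,
                             variant = c("rational", "exponential"),
                             log_domain = TRUE, offset = 1e-6) {
  variant <- match.arg(variant)
  if (!identical(k, "auto")) {
    if (!is.numeric(k) || length(k) != 1L || k <= 0) {
      stop("k must be \"auto\" or a single value > 0", call. = FALSE)
    }
  }
  if (lambda <= 0 || lambda > 0.25) {
    stop("lambda must be in (0, 0.25]", call. = FALSE)
  }
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  structure(list(k = k, lambda = lambda, iterations = as.integer(iterations),
                 variant = variant, log_domain = log_domain, offset = offset),
            class = "diffusion_params")
}

#' Perona-Malik diffusion coefficient
#'
#' Both variants equal 1 at zero gradient (diffusion enhanced in flat
#' regions) and decay monotonically with gradient magnitude (diffusion
#' suppressed across edges).
#'
#' @param grad_mag Gradient magnitude(s), >= 0.
#' @param k Edge-stopping threshold, > 0.
#' @param variant `"rational"` or `"exponential"`.
#' @return Coefficient(s) in `(0, 1]`.
#' @export
diffusion_coefficient <- function(grad_mag, k,
                                  variant = c("rational", "exponential")) {
  variant <- match.arg(variant)
  if (any(grad_mag < 0)) stop("grad_mag must be >= 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  r <- (grad_mag / k)^2
  switch(variant, rational = 1 / (1 + r), exponential = exp(-r))
}

# 90th percentile of non-zero 4-neighbour gradient magnitudes.
auto_k <- function(img) {
  gr <- abs(img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE])
  gc <- abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE])
  g <- c(gr, gc)
  g <- g[g > 0]
  if (!length(g)) return(1e-3)
  as.numeric(stats::quantile(g, 0.9, names = FALSE))
}

#' One explicit Perona-Malik diffusion step
#'
#' Updates `I(x) <- I(x) + lambda * sum_p c(|dI|) * dI` over the
#' 4-neighbourhood, with `dI = I(p) - I(x)` and replicated (zero-flux)
#' borders, so constants are fixed points and the global mean is conserved.
#'
#' @param image Numeric matrix.
#' @param k Edge threshold (> 0).
#' @param lambda Step weight in `(0, 0.25]`.
#' @param variant Coefficient variant; see [diffusion_coefficient()].
#' @return Updated matrix.
#' @export
pm_step <- function(image, k, lambda = 0.2,
                    variant = c("rational", "exponential")) {
  variant <- match.arg(variant)
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  flux <- matrix(0, nrow(image), ncol(image))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    grad <- shift_replicate(image, d[1L], d[2L]) - image
    flux <- flux + diffusion_coefficient(abs(grad), k, variant) * grad
  }
  image + lambda * flux
}

#' Perona-Malik anisotropic diffusion denoising
#'
#' Iterates [pm_step()] from the input image. With `log_domain = TRUE` the
#' image is log-transformed first (multiplicative speckle becomes additive)
#' and exponentiated back afterwards.
#'
#' @param image Non-negative image matrix.
#' @param params A [diffusion_params()] object.
#' @return Denoised image matrix.
#' @export
denoise_pm <- function(image, params = diffusion_params()) {
  validate_gray_image(image, "image")
  if (params$iterations == 0L) return(image)
  work <- if (params$log_domain) log_transform(image, params$offset) else image
  k <- if (identical(params$k, "auto")) auto_k(work) else params$k
  if (params$iterations > 0L) {
    for (i in seq_len(params$iterations)) {
      work <- pm_step(work, k, params$lambda, params$variant)
    }
  }
  if (params$log_domain) {
    pmax(inverse_log_transform(work, params$offset), 0)
  } else {
    work
  }
}
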