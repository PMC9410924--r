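#' Rayleigh probability density of the speckle envelope
#'
#' Under fully developed speckle the echo's real and imaginary parts are
#' independent zero-mean Gaussians with variance `sigma^2`, and the envelope
#' `M = sqrt(Mr^2 + Mi^2)` is Rayleigh distributed:
#' `p(m) = (m / sigma^2) exp(-m^2 / (2 sigma^2))` for `m >= 0`, 0 otherwise.
#'
#' @param m Envelope value(s); finite numeric.
#' @param sigma Scale parameter of the component Gaussians, > 0.
#' @return Density value(s), >= 0.
#' @export
rayleigh_pdf <- function(m, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single finite value > 0", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("m must be finite", call. = FALSE)
  ifelse(m < 0, 0, (m / sigma^2) * exp(-m^2 / (2 * sigma^2)))
}

#' Sample a complex speckle field
#'
#' Draws independent zero-mean Gaussian real and imaginary components with
#' standard deviation `sigma` per pixel and forms the Rayleigh envelope.
#'
#' @param shape Integer vector `c(h, w)`.
#' @param sigma Gaussian component scale, > 0.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return An object of class `speckle_field`: list with `mr`, `mi`,
#'   `envelope` (matrices) and `sigma`.
#' @export
sample_speckle_field <- function(shape, sigma, seed = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) {
    stop("shape must be two positive integers", call. = FALSE)
  }
  with_seed_if(seed, {
    n <- shape[1L] * shape[2L]
    mr <- matrix(stats::rnorm(n, 0, sigma), shape[1L], shape[2L])
    mi <- matrix(stats::rnorm(n, 0, sigma), shape[1L], shape[2L])
    structure(
      list(mr = mr, mi = mi, envelope = sqrt(mr^2 + mi^2), sigma = sigma),
      class = "speckle_field"
    )
  })
}

#' Corrupt a clean image with multiplicative speckle
#'
#' Forms `P' = P * N` where `N` is the sampled envelope. With
#' `normalize = TRUE` (default) the envelope is divided by its theoretical
#' mean `sigma * sqrt(pi / 2)` so the expected brightness of the noisy image
#' matches the clean one.
#'
#' @param clean Clean image (numeric matrix).
#' @param field A `speckle_field` from [sample_speckle_field()].
#' @param normalize Divide the envelope by its theoretical mean first.
#' @return Noisy image matrix (>= 0).
#' @export
apply_multiplicative_noise <- function(clean, field, normalize = TRUE) {
  validate_gray_image(clean, "clean")
  env <- field$envelope
  check_same_shape(clean, env)
  if (normalize) env <- env / (field$sigma * sqrt(pi / 2))
  pmax(clean * env, 0)
}

#' Logarithmic transform of an image (and its inverse)
#'
#' `log_transform` maps multiplicative speckle to additive noise:
#' `ln(P * N) = ln P + ln N`. A small offset keeps `ln` defined at zero
#' intensity; the inverse subtracts it back.
#'
#' @param image Non-negative image matrix.
#' @param offset Small positive stabiliser added before the log
#'   (default `1e-6` on the `[0, 1]` intensity scale).
#' @return Transformed matrix.
#' @export
log_transform <- function(image, offset = 1e-6) {
  validate_gray_image(image, "image")
  if (offset <= 0) stop("offset must be > 0", call. = FALSE)
  log(image + offset)
}

#' @rdname log_transform
#' @export
inverse_log_transform <- function(image, offset = 1e-6) {
  if (offset <= 0) stop("offset must be > 0", call. = FALSE)
  exp(image) - offset
}

#' Describe the phantom object geometry
#'
#' The phantom object is a "bean": an ellipse whose boundary radius is
#' reduced by a cosine-squared indentation on one side, mimicking the hilum
#' of a kidney outline. `indent = 0` gives an exact axis-aligned ellipse.
#'
#' @param shape Frame shape `c(h, w)`; used for proportional defaults.
#' @param center Object centre `(row, col)` in continuous coordinates
#'   (default: frame centre).
#' @param semi_axes Semi-axes `(rows, cols)` in pixels (default roughly
#'   0.21 h x 0.33 w, an elongated organ filling ~20% of the frame).
#' @param indent Indentation depth as a fraction of the local radius, in
#'   `[0, 0.8]` (default 0.25).
#' @return A list describing the object.
#' @export
phantom_object <- function(shape = c(96L, 96L), center = shape / 2,
                           semi_axes = c(0.21, 0.33) * shape,
                           indent = 0.25) {
  if (indent < 0 || indent > 0.8) {
    stop("indent must be in [0, 0.8]", call. = FALSE)
  }
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0", call. = FALSE)
  list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
       indent = as.numeric(indent))
}

# Binary mask of the bean/ellipse on a 0-based, row-major pixel grid;
# pixel (r, c) is tested at its centre (r + 0.5, c + 0.5).
object_mask <- function(shape, object) {
  h <- shape[1L]
  w <- shape[2L]
  rr <- matrix(seq_len(h) - 0.5, h, w)
  cc <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE)
  nv <- (rr - object$center[1L]) / object$semi_axes[1L]
  nu <- (cc - object$center[2L]) / object$semi_axes[2L]
  rho <- sqrt(nu^2 + nv^2)
  th <- atan2(nv, nu)
  edge <- 1 - object$indent * pmax(cos(th), 0)^2
  matrix(as.integer(rho <= edge), h, w)
}

#' Generate a synthetic speckled ultrasound phantom
#'
#' Produces a smooth dark organ-like region on a brighter background
#' (B-mode renal convention), corrupts it with multiplicative
#' Rayleigh-envelope speckle, and retains the true (unblurred) mask.
#'
#' @param shape Frame shape `c(h, w)`.
#' @param object Object geometry from [phantom_object()].
#' @param contrast Named vector `c(interior=, background=)` intensities in
#'   `[0, 1]`.
#' @param sigma Speckle scale; `0` disables noise.
#' @param blur_sd Gaussian blur (pixels) applied to the clean image to
#'   create soft edges; the truth mask is not blurred.
#' @param seed Integer seed; the whole phantom is reproducible from it.
#' @param normalize Passed to [apply_multiplicative_noise()].
#' @return Object of class `speckle_phantom`: `clean`, `truth_mask`,
#'   `noisy`, `sigma`, `blur_sd`, `seed`, `object`, `contrast`.
#' @export
generate_phantom <- function(shape = c(96L, 96L),
                             object = phantom_object(shape),
                             contrast = c(interior = 0.3, background = 0.7),
                             sigma = 1.0, blur_sd = 1.5, seed = 1L,
                             normalize = TRUE) {
  shape <- as.integer(shape)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  lo <- object$center - object$semi_axes
  hi <- object$center + object$semi_axes
  if (lo[1L] < 2 || lo[2L] < 2 || hi[1L] > shape[1L] - 2 ||
      hi[2L] > shape[2L] - 2) {
    stop("object must fit inside the frame with a 2-pixel margin",
         call. = FALSE)
  }
  mask <- object_mask(shape, object)
  clean <- matrix(contrast[["background"]], shape[1L], shape[2L])
  clean[mask == 1L] <- contrast[["interior"]]
  clean <- gaussian_blur(clean, blur_sd)
  noisy <- if (sigma == 0) {
    clean
  } else {
    with_seed_if(seed, {
      field <- sample_speckle_field(shape, sigma)
      apply_multiplicative_noise(clean, field, normalize = normalize)
    })
  }
  structure(
    list(clean = clean, truth_mask = mask, noisy = noisy, sigma = sigma,
         blur_sd = blur_sd, seed = as.integer(seed), object = object,
         contrast = contrast),
    class = "speckle_phantom"
  )
}

#' @export
print.speckle_phantom <- function(x, ...) {
  cat(sprintf(
    "speckle_phantom %dx%d  sigma=%g  seed=%d  object area=%d px\n",
    nrow(x$clean), ncol(x$clean), x$sigma, x$seed, sum(x$truth_mask)))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes `noisy.png`, `clean.png` (intensities clamped to `[0, 1]`),
#' `mask.png` (0/255) and a `phantom.json` sidecar with shape, sigma, seed
#' and object geometry.
#'
#' @param phantom A `speckle_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray_image(phantom$noisy, file.path(dir, "noisy.png"))
  write_gray_image(phantom$clean, file.path(dir, "clean.png"))
  write_mask(phantom$truth_mask, file.path(dir, "mask.png"))
  meta <- list(shape = dim(phantom$clean), sigma = phantom$sigma,
               blur_sd = phantom$blur_sd, seed = phantom$seed,
               object = phantom$object,
               contrast = as.list(phantom$contrast))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
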