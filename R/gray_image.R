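#' Validate a grayscale image
#'
#' Images are plain numeric matrices with intensities stored on a
#' dimensionless scale, internally `[0, 1]` for phantoms (speckle can push
#' values above 1; only finiteness and non-negativity are enforced).
#'
#' @param img Numeric matrix, at least 3x3, all values finite and >= 0.
#' @param name Name used in error messages.
#' @return The validated matrix, invisibly usable as-is.
#' @export
validate_gray_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(name, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop(name, " must be at least 3x3", call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(name, " must contain only finite values", call. = FALSE)
  }
  if (any(img < 0)) {
    stop(name, " must be non-negative", call. = FALSE)
  }
  img
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " must share the same shape (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel images are averaged to one channel. Values are returned on
#' the `[0, 1]` scale (as decoded by the PNG/TIFF readers).
#'
#' @param path File path; format chosen by extension (.png, .tif/.tiff).
#' @return Numeric matrix (rows = image rows).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  validate_gray_image(arr, path)
}

#' Write a grayscale image to PNG
#'
#' Values are clamped to `[0, 1]` before encoding.
#'
#' @param img Numeric matrix.
#' @param path Output path (PNG).
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  png::writePNG(clamp(img, 0, 1), path, dpi = NULL,
                asp = NULL, text = NULL)
  invisible(path)
}

#' Read / write a binary mask as a 0/255 PNG
#'
#' @param mask Binary (0/1) matrix.
#' @param path File path.
#' @return `read_mask`: integer 0/1 matrix; `write_mask`: `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- validate_binary_mask(mask, "mask")
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  m <- matrix(as.integer(img > 0.5), nrow(img), ncol(img))
  m
}

validate_binary_mask <- function(mask, name = "mask") {
  if (is.logical(mask)) {
    mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  }
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    stop(name, " must be a binary (0/1) matrix", call. = FALSE)
  }
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}
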