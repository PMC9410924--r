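#' Closed contours
#'
#' A contour is an ordered set of `n >= 4` subpixel `(row, col)` points,
#' implicitly closed (the last point connects back to the first).
#' Coordinates follow the pixel-centre convention: the 0-based pixel
#' `(r, c)` is centred at `(r + 0.5, c + 0.5)`, so a `h x w` image spans
#' `[0, h] x [0, w]`.
#'
#' @param pts Numeric `n x 2` matrix of `(row, col)` points.
#' @return The points with class `contour`.
#' @export
as_contour <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L || nrow(pts) < 4L) {
    stop("a contour needs an n x 2 matrix with n >= 4", call. = FALSE)
  }
  if (!all(is.finite(pts))) stop("contour points must be finite", call. = FALSE)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  if (any(rowSums((nxt - pts)^2) == 0)) {
    stop("no two consecutive contour points may coincide", call. = FALSE)
  }
  colnames(pts) <- c("row", "col")
  structure(pts, class = c("contour", class(pts)))
}

#' Signed and absolute area of a closed contour
#'
#' Shoelace formula on `(col, row)`; a positive signed area corresponds to
#' a clockwise contour in display orientation (rows increasing downwards).
#'
#' @param contour An `n x 2` `(row, col)` point matrix.
#' @param signed Return the signed value.
#' @return Area in pixel^2.
#' @export
contour_area <- function(contour, signed = FALSE) {
  r <- contour[, 1L]
  cc <- contour[, 2L]
  r2 <- c(r[-1L], r[1L])
  c2 <- c(cc[-1L], cc[1L])
  a <- 0.5 * sum(cc * r2 - c2 * r)
  if (signed) a else abs(a)
}

ensure_clockwise <- function(pts) {
  if (contour_area(pts, signed = TRUE) < 0) pts[rev(seq_len(nrow(pts))), ] else pts
}

#' Resample a closed contour to equally spaced points
#'
#' Linear interpolation along the closed polygon at `n` equal arc-length
#' stations, starting at the first point.
#'
#' @param contour Point matrix.
#' @param n Number of output points (>= 4).
#' @return A [as_contour()] object with `n` points.
#' @export
resample_contour <- function(contour, n = 100L) {
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4", call. = FALSE)
  pts <- rbind(contour, contour[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- total * (seq_len(n) - 1L) / n
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- (target - s[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  out <- pts[idx, , drop = FALSE] +
    frac * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
  as_contour(out)
}

#' Outward unit normals of a closed contour
#'
#' Normals are perpendicular to the central-difference tangents, with the
#' sign chosen to point away from the contour centroid (adequate for the
#' star-shaped organ outlines this package segments).
#'
#' @param contour Point matrix.
#' @return `n x 2` matrix of unit `(row, col)` normal vectors.
#' @export
contour_normals <- function(contour) {
  pts <- unclass(contour)
  n <- nrow(pts)
  nxt <- pts[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  prv <- pts[c(n, seq_len(n)[-n]), , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(tang[, 2L], -tang[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  centroid <- colMeans(pts)
  flip <- rowSums(nrm * sweep(pts, 2L, centroid)) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  nrm
}

#' Rasterise a closed contour to a binary mask
#'
#' A pixel is foreground iff its centre lies inside the polygon under the
#' even-odd rule (scanline implementation).
#'
#' @param contour Point matrix.
#' @param shape Output shape `c(h, w)`.
#' @return Integer 0/1 matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  h <- as.integer(shape[1L])
  w <- as.integer(shape[2L])
  mask <- matrix(0L, h, w)
  r1 <- contour[, 1L]
  c1 <- contour[, 2L]
  r2 <- c(r1[-1L], r1[1L])
  c2 <- c(c1[-1L], c1[1L])
  for (i in seq_len(h)) {
    y <- i - 0.5
    hit <- which((r1 <= y & r2 > y) | (r2 <= y & r1 > y))
    if (length(hit) < 2L) next
    xc <- sort(c1[hit] + (y - r1[hit]) / (r2[hit] - r1[hit]) *
                 (c2[hit] - c1[hit]))
    if (length(xc) %% 2L == 1L) xc <- xc[-length(xc)]
    for (k in seq(1L, length(xc), by = 2L)) {
      j0 <- max(floor(xc[k] + 0.5) + 1L, 1L)
      j1 <- min(ceiling(xc[k + 1L] + 0.5) - 1L, w)
      if (j1 >= j0) mask[i, j0:j1] <- 1L
    }
  }
  mask
}

#' Read / write a contour as CSV
#'
#' The CSV has columns `index,row,col`: 0-based point index and subpixel
#' coordinates in the pixel-centre convention.
#'
#' @param contour Point matrix.
#' @param path File path.
#' @return `read_contour_csv`: a [as_contour()]; `write_contour_csv`:
#'   `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(index = seq_len(nrow(contour)) - 1L,
                   row = contour[, 1L], col = contour[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  as_contour(cbind(df$row, df$col))
}
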