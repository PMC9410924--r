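#' Parameters of the parametric active contour (Snake)
#'
#' The Snake minimises the discrete energy
#' `sum_i [ 1/2 (alpha |v_{i+1}-v_i|^2 + beta |v_{i+1}-2v_i+v_{i-1}|^2)
#'          + kappa E_ext(v_i) ]`
#' over a closed contour, by semi-implicit Euler-Lagrange iteration.
#'
#' @param alpha Elasticity weight (>= 0).
#' @param beta Rigidity weight (>= 0).
#' @param gamma Evolution step weight (> 0); larger is more conservative.
#' @param kappa External-force weight (>= 0).
#' @param edge_sigma Gaussian pre-smoothing scale (pixels) of the edge map.
#' @param max_iter Iteration budget.
#' @param tol Convergence threshold on the mean point displacement (pixels).
#' @param resample_every Iterations between equal-arc-length resampling;
#'   set above `max_iter` to disable.
#' @return A list of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.05, gamma = 1.0, kappa = 2.0,
                         edge_sigma = 2.0, max_iter = 500L, tol = 0.05,
                         resample_every = 25L) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (alpha < 0 || beta < 0 || kappa < 0 || alpha + beta + kappa <= 0) {
    stop("alpha, beta, kappa must be >= 0 with a positive sum", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 edge_sigma = edge_sigma, max_iter = as.integer(max_iter),
                 tol = tol, resample_every = as.integer(resample_every)),
            class = "snake_params")
}

#' Discrete internal (smoothness) energy of a closed contour
#'
#' `1/2 sum_i [ alpha |v_{i+1} - v_i|^2 + beta |v_{i+1} - 2 v_i + v_{i-1}|^2 ]`
#' with cyclic indexing; translation invariant by construction.
#'
#' @param contour Point matrix.
#' @param alpha,beta Elasticity / rigidity weights.
#' @return Energy value.
#' @export
internal_energy <- function(contour, alpha, beta) {
  pts <- unclass(contour)
  n <- nrow(pts)
  nxt <- pts[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  prv <- pts[c(n, seq_len(n)[-n]), , drop = FALSE]
  d1 <- nxt - pts
  d2 <- nxt - 2 * pts + prv
  0.5 * (alpha * sum(d1^2) + beta * sum(d2^2))
}

#' Edge potential of an image and its force field
#'
#' The external energy is the classical edge functional
#' `E_ext = -|grad(G_sigma * I)|^2`, whose minima sit on intensity edges.
#' With `normalize = TRUE` (default) the potential is divided by its
#' maximum magnitude so it spans `[-1, 0]`, making the energy weights
#' comparable across images of different contrast. The force is
#' `F_ext = -grad E_ext`, realised by central differences and sampled at
#' subpixel contour points by bilinear interpolation.
#'
#' @param image Image matrix.
#' @param edge_sigma Gaussian smoothing scale (pixels).
#' @param normalize Scale the potential to `[-1, 0]`.
#' @return A list of class `edge_potential`: `potential`, `force_row`,
#'   `force_col` (matrices).
#' @export
edge_potential <- function(image, edge_sigma = 2.0, normalize = TRUE) {
  validate_gray_image(image, "image")
  sm <- gaussian_blur(image, edge_sigma)
  gr <- (shift_replicate(sm, 1L, 0L) - shift_replicate(sm, -1L, 0L)) / 2
  gc <- (shift_replicate(sm, 0L, 1L) - shift_replicate(sm, 0L, -1L)) / 2
  e <- -(gr^2 + gc^2)
  if (normalize && min(e) < 0) e <- e / abs(min(e))
  frow <- -(shift_replicate(e, 1L, 0L) - shift_replicate(e, -1L, 0L)) / 2
  fcol <- -(shift_replicate(e, 0L, 1L) - shift_replicate(e, 0L, -1L)) / 2
  structure(list(potential = e, force_row = frow, force_col = fcol,
                 edge_sigma = edge_sigma),
            class = "edge_potential")
}

#' Total discrete Snake energy
#'
#' Internal energy plus `kappa` times the external potential sampled
#' bilinearly at the contour points. This is the objective shared by
#' [evolve_snake()] and the cloud-model optimiser [optimize_contour()].
#'
#' @param contour Point matrix.
#' @param image Image matrix (ignored when `edge` is supplied).
#' @param params A [snake_params()] object.
#' @param edge Optional precomputed [edge_potential()].
#' @return Energy value.
#' @export
snake_energy <- function(contour, image = NULL, params = snake_params(),
                         edge = NULL) {
  if (is.null(edge)) edge <- edge_potential(image, params$edge_sigma)
  internal_energy(contour, params$alpha, params$beta) +
    params$kappa * sum(bilinear_sample(edge$potential, contour))
}

#' Cyclic internal-force matrix of the Snake
#'
#' The gradient of the internal energy is `A v`, with the cyclic
#' pentadiagonal stencil `(beta, -(alpha + 4 beta), 2 alpha + 6 beta,
#' -(alpha + 4 beta), beta)`.
#'
#' @param n Number of contour points.
#' @param alpha,beta Weights.
#' @return `n x n` matrix.
#' @export
snake_matrix <- function(n, alpha, beta) {
  a <- matrix(0, n, n)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    a[i, idx(i - 2L)] <- a[i, idx(i - 2L)] + beta
    a[i, idx(i - 1L)] <- a[i, idx(i - 1L)] - (alpha + 4 * beta)
    a[i, i] <- a[i, i] + 2 * alpha + 6 * beta
    a[i, idx(i + 1L)] <- a[i, idx(i + 1L)] - (alpha + 4 * beta)
    a[i, idx(i + 2L)] <- a[i, idx(i + 2L)] + beta
  }
  a
}

#' Evolve a Snake contour by semi-implicit iteration
#'
#' Each step solves the two independent linear systems (one per
#' coordinate) `(A + gamma I) x' = gamma x + kappa F_x(v)`, the
#' semi-implicit discretisation of the Euler-Lagrange force balance
#' `F_int + F_ext = 0`; a fixed point satisfies `A x = kappa F_x`.
#' The contour is resampled to equal arc length every `resample_every`
#' iterations and points are clamped to the image bounds. Iteration stops
#' when the mean point displacement drops below `tol`.
#'
#' @param contour Initial closed contour.
#' @param image Image matrix (used when `edge` is not supplied).
#' @param params A [snake_params()] object.
#' @param edge Optional precomputed [edge_potential()].
#' @return A list of class `segmentation_result`: `contour`, `mask`,
#'   `trace` (data.frame `iter,total_energy,internal,external,mean_disp`),
#'   `converged`, `iterations`, `energy`.
#' @export
evolve_snake <- function(contour, image, params = snake_params(),
                         edge = NULL) {
  pts <- unclass(as_contour(contour))
  if (is.null(edge)) edge <- edge_potential(image, params$edge_sigma)
  h <- nrow(edge$potential)
  w <- ncol(edge$potential)
  n <- nrow(pts)
  a <- snake_matrix(n, params$alpha, params$beta)
  m <- a + diag(params$gamma, n)
  minv <- tryCatch(solve(m), error = function(e) {
    stop("singular evolution system; increase gamma or alpha/beta",
         call. = FALSE)
  })
  trace <- vector("list", params$max_iter)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(params$max_iter)) {
    fr <- bilinear_sample(edge$force_row, pts)
    fc <- bilinear_sample(edge$force_col, pts)
    newr <- minv %*% (params$gamma * pts[, 1L] + params$kappa * fr)
    newc <- minv %*% (params$gamma * pts[, 2L] + params$kappa * fc)
    newpts <- cbind(clamp(as.numeric(newr), 0.5, h - 0.5),
                    clamp(as.numeric(newc), 0.5, w - 0.5))
    disp <- mean(sqrt(rowSums((newpts - pts)^2)))
    pts <- newpts
    eint <- internal_energy(pts, params$alpha, params$beta)
    eext <- sum(bilinear_sample(edge$potential, pts))
    trace[[t]] <- c(iter = t, total_energy = eint + params$kappa * eext,
                    internal = eint, external = eext, mean_disp = disp)
    iter <- t
    if (disp < params$tol) {
      converged <- TRUE
      break
    }
    if (t %% params$resample_every == 0L) {
      pts <- unclass(resample_contour(pts, n))
    }
  }
  trace <- as.data.frame(do.call(rbind, trace[seq_len(iter)]))
  ct <- as_contour(pts)
  structure(list(contour = ct, mask = contour_to_mask(ct, c(h, w)),
                 trace = trace, converged = converged, iterations = iter,
                 energy = trace$total_energy[iter]),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d points, %d iterations, %sconverged, energy %.4g\n",
    nrow(x$contour), x$iterations, if (x$converged) "" else "NOT ",
    x$energy))
  invisible(x)
}
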