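#' Default PCNN coupling kernel
#'
#' 3x3 inverse-square-distance weights with a zero centre, used for both
#' the feeding (`M`) and linking (`W`) couplings.
#'
#' @return 3x3 numeric matrix.
#' @export
pcnn_kernel <- function() {
  k <- matrix(c(0.5, 1, 0.5, 1, 0, 1, 0.5, 1, 0.5), 3L, 3L)
  k
}

#' Pulse-coupled neural network parameters
#'
#' One neuron per pixel, with feeding input `F`, linking input `L`,
#' internal activity `U = F (1 + beta L)` and a decaying dynamic threshold
#' `theta` that recharges by `vtheta` when the neuron fires. The decay
#' arguments are the per-iteration multiplicative factors (`e^{-a}` of the
#' underlying exponential decays).
#'
#' @param beta Linking strength.
#' @param decay_f,decay_l,decay_theta Per-iteration decay factors of `F`,
#'   `L` and `theta`, each in `(0, 1)`.
#' @param vf,vl Amplification of the feeding / linking couplings (>= 0).
#' @param vtheta Threshold recharge after firing (> 0).
#' @param kernel_m,kernel_w Feeding / linking kernels: odd-sized,
#'   non-negative, zero centre.
#' @param theta0 Initial threshold (applied uniformly).
#' @param max_iter Iteration budget.
#' @return A list of class `pcnn_params`.
#' @export
pcnn_params <- function(beta = 0.2, decay_f = 0.3, decay_l = 0.3,
                        decay_theta = 0.9, vf = 0.01, vl = 1.0,
                        vtheta = 20, kernel_m = pcnn_kernel(),
                        kernel_w = pcnn_kernel(), theta0 = 1.0,
                        max_iter = 60L) {
  for (d in c(decay_f, decay_l, decay_theta)) {
    if (d <= 0 || d >= 1) stop("decay factors must be in (0, 1)", call. = FALSE)
  }
  if (vtheta <= 0) stop("vtheta must be > 0 (threshold must recharge)",
                        call. = FALSE)
  if (vf < 0 || vl < 0) stop("vf and vl must be >= 0", call. = FALSE)
  for (k in list(kernel_m, kernel_w)) {
    ctr <- (dim(k) + 1L) / 2L
    if (any(k < 0) || k[ctr[1L], ctr[2L]] != 0) {
      stop("kernels must be non-negative with a zero centre", call. = FALSE)
    }
  }
  structure(list(beta = beta, decay_f = decay_f, decay_l = decay_l,
                 decay_theta = decay_theta, vf = vf, vl = vl,
                 vtheta = vtheta, kernel_m = kernel_m, kernel_w = kernel_w,
                 theta0 = theta0, max_iter = as.integer(max_iter)),
            class = "pcnn_params")
}

#' Initial PCNN state
#'
#' `F = L = U = 0`, `theta = theta0`, nothing fired.
#'
#' @param shape Image shape `c(h, w)`.
#' @param params A [pcnn_params()] object.
#' @return A list of class `pcnn_state` with fields `f`, `l`, `u`, `theta`,
#'   `y` and the iteration counter `iter`.
#' @export
pcnn_init <- function(shape, params) {
  z <- matrix(0, shape[1L], shape[2L])
  structure(list(f = z, l = z, u = z,
                 theta = matrix(params$theta0, shape[1L], shape[2L]),
                 y = matrix(0L, shape[1L], shape[2L]), iter = 0L),
            class = "pcnn_state")
}

#' One synchronous PCNN iteration
#'
#' Updates, in order:
#' `F <- decay_f F + S + vf (M (*) Y)`,
#' `L <- decay_l L + vl (W (*) Y)`,
#' `U <- F (1 + beta L)`,
#' `Y <- 1[U > theta]`,
#' `theta <- decay_theta theta + vtheta Y`,
#' where `S` is the stimulus and `(*)` is 2D correlation with replicated
#' borders; the threshold comparison uses the previous iteration's theta.
#'
#' @param state A `pcnn_state`.
#' @param stimulus Stimulus image (matrix), same shape as the state.
#' @param params A [pcnn_params()] object.
#' @return The updated `pcnn_state`.
#' @export
pcnn_step <- function(state, stimulus, params) {
  check_same_shape(state$f, stimulus, "state and stimulus")
  yprev <- state$y
  f <- params$decay_f * state$f + stimulus +
    params$vf * correlate_replicate(yprev, params$kernel_m)
  l <- params$decay_l * state$l +
    params$vl * correlate_replicate(yprev, params$kernel_w)
  u <- f * (1 + params$beta * l)
  y <- matrix(as.integer(u > state$theta), nrow(u), ncol(u))
  theta <- params$decay_theta * state$theta + params$vtheta * y
  structure(list(f = f, l = l, u = u, theta = theta, y = y,
                 iter = state$iter + 1L),
            class = "pcnn_state")
}

#' Run the PCNN over an image
#'
#' Iterates [pcnn_step()] from the zero state, recording the fired map of
#' every iteration and the iteration at which each pixel first fired.
#' Because the threshold decays geometrically while the feeding input
#' accumulates the stimulus, every pixel with positive stimulus eventually
#' fires; pixels that have not fired within `max_iter` are flagged.
#'
#' @param image Stimulus image, typically scaled to `[0, 1]`.
#' @param params A [pcnn_params()] object.
#' @param stop_when_all_fired Stop early once every pixel has fired once.
#' @return A list of class `pcnn_run`: `fired` (list of 0/1 matrices),
#'   `first_fire` (matrix of first-firing iterations, `NA` if never),
#'   `n_iter`, `all_fired`.
#' @export
run_pcnn <- function(image, params = pcnn_params(),
                     stop_when_all_fired = TRUE) {
  validate_gray_image(image, "image")
  if (params$max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  state <- pcnn_init(dim(image), params)
  fired <- vector("list", params$max_iter)
  first <- matrix(NA_integer_, nrow(image), ncol(image))
  for (a in seq_len(params$max_iter)) {
    state <- pcnn_step(state, image, params)
    fired[[a]] <- state$y
    newly <- is.na(first) & state$y == 1L
    first[newly] <- a
    if (stop_when_all_fired && !anyNA(first)) {
      fired <- fired[seq_len(a)]
      break
    }
  }
  structure(list(fired = fired, first_fire = first,
                 n_iter = length(fired), all_fired = !anyNA(first)),
            class = "pcnn_run")
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log(p[ok]) - (1 - p[ok]) * log(1 - p[ok])
  h
}

#' Select the segmentation iteration of a PCNN run
#'
#' Scores each candidate fired map and returns the best one. The default
#' criterion is the Shannon entropy of the binary map (maximal when the
#' fired fraction is nearest 1/2), computed on the per-iteration pulse maps;
#' `"entropy_cumulative"` applies the same score to the cumulative
#' fired-by-now maps, which isolates the earliest-firing intensity class
#' plus everything before it. Ties are broken by the earliest iteration;
#' all-0 / all-1 maps are never candidates.
#'
#' @param run A `pcnn_run`.
#' @param criterion `"entropy"`, `"entropy_cumulative"` or
#'   `"first_fire_otsu"`.
#' @return Integer 0/1 matrix, with attribute `"iteration"` (the selected
#'   iteration, or for the Otsu criterion the first-fire threshold).
#' @export
select_segment_iteration <- function(run,
                                     criterion = c("entropy",
                                                   "entropy_cumulative",
                                                   "first_fire_otsu")) {
  criterion <- match.arg(criterion)
  if (criterion == "first_fire_otsu") {
    thr <- otsu_first_fire(run)
    out <- matrix(as.integer(!is.na(run$first_fire) &
                               run$first_fire <= thr),
                  nrow(run$first_fire), ncol(run$first_fire))
    if (all(out == 0L) || all(out == 1L)) {
      stop("no non-trivial fired map to segment from", call. = FALSE)
    }
    attr(out, "iteration") <- thr
    return(out)
  }
  maps <- run$fired
  if (criterion == "entropy_cumulative") {
    acc <- maps[[1L]]
    maps <- vector("list", length(run$fired))
    maps[[1L]] <- acc
    for (a in seq_along(run$fired)[-1L]) {
      acc <- pmax(acc, run$fired[[a]])
      maps[[a]] <- acc
    }
  }
  p <- vapply(maps, mean, numeric(1L))
  ok <- p > 0 & p < 1
  if (!any(ok)) {
    stop("no non-trivial fired map to segment from", call. = FALSE)
  }
  score <- binary_entropy(p)
  score[!ok] <- -Inf
  best <- which.max(score)   # which.max returns the earliest maximum
  out <- maps[[best]]
  attr(out, "iteration") <- best
  out
}

# Otsu threshold on first-fire iterations: the two intensity classes fire
# as two temporal modes; the split maximising the between-class variance
# isolates the earliest-firing class. Never-fired pixels count as one
# iteration past the end.
otsu_first_fire <- function(run) {
  v <- as.numeric(run$first_fire)
  v[is.na(v)] <- run$n_iter + 1
  lev <- sort(unique(v))
  if (length(lev) == 1L) {
    stop("no non-trivial fired map to segment from", call. = FALSE)
  }
  best <- -Inf
  thr <- lev[1L]
  for (t in lev[-length(lev)]) {
    lo <- v <= t
    w0 <- mean(lo)
    bc <- w0 * (1 - w0) * (mean(v[!lo]) - mean(v[lo]))^2
    if (bc > best) {
      best <- bc
      thr <- t
    }
  }
  as.integer(thr)
}

#' Extract an initial closed contour from a binary mask
#'
#' Keeps the largest 4-connected component with area >= `min_area`, fills
#' its holes, applies one 3x3 binary opening, traces the outer boundary of
#' the (largest surviving) component, offsets the traced polygon half a
#' pixel along the outward normals so it follows the outer pixel edge, and
#' resamples to `n_points` equally spaced points. The result is a closed,
#' clockwise contour suitable as a Snake initialisation.
#'
#' @param mask Binary 0/1 matrix.
#' @param min_area Minimum component area in pixels.
#' @param n_points Number of contour points after resampling.
#' @return A [as_contour()] object.
#' @export
extract_initial_contour <- function(mask, min_area = 25L, n_points = 100L) {
  mask <- validate_binary_mask(mask)
  comp <- largest_component(mask, min_area)
  comp <- matrix(as.integer(EBImage::fillHull(comp) > 0), nrow(comp),
                 ncol(comp))
  kern <- EBImage::makeBrush(3L, shape = "box")
  comp <- matrix(as.integer(EBImage::opening(comp, kern) > 0), nrow(comp),
                 ncol(comp))
  if (sum(comp) < max(min_area, 4L)) {
    stop("no component of at least min_area pixels after opening",
         call. = FALSE)
  }
  comp <- largest_component(comp, 1L)
  oc <- EBImage::ocontour(comp)[[1L]]   # ordered boundary pixels, 0-based
  pts <- cbind(oc[, 1L] + 0.5, oc[, 2L] + 0.5)
  keep <- c(TRUE, rowSums(diff(pts)^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (all(pts[1L, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 4L) stop("degenerate component boundary", call. = FALSE)
  pts <- ensure_clockwise(pts)
  pts <- pts + 0.5 * contour_normals(as_contour(pts))
  resample_contour(as_contour(pts), n_points)
}

# Largest 4-connected component as a 0/1 matrix; errors below min_area.
largest_component <- function(mask, min_area) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 1L) stop("mask is empty", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  if (max(sizes) < min_area) {
    stop("no component of at least min_area pixels", call. = FALSE)
  }
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}
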