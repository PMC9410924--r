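#' Cloud model digital characteristics
#'
#' A normal cloud is parameterised by its expectation `Ex` (the concept
#' centre), entropy `En > 0` (dispersion of the drops) and hyper-entropy
#' `He >= 0` (dispersion of the dispersion: the "thickness" of the cloud).
#'
#' @param ex Expectation.
#' @param en Entropy, > 0.
#' @param he Hyper-entropy, >= 0.
#' @return A list of class `cloud_params`.
#' @export
cloud_params <- function(ex = 0, en = 1, he = 0) {
  if (en <= 0) stop("en must be > 0", call. = FALSE)
  if (he < 0) stop("he must be >= 0", call. = FALSE)
  structure(list(ex = ex, en = en, he = he), class = "cloud_params")
}

# Additive cloud noise around 0: En' ~ N(en, he^2) truncated to > 0,
# x ~ N(0, En'^2). Shared by the generator and the DE perturbation.
cloud_noise <- function(n, en, he) {
  enp <- if (he > 0) stats::rnorm(n, en, he) else rep.int(en, n)
  bad <- which(enp <= 0)
  while (length(bad)) {
    enp[bad] <- stats::rnorm(length(bad), en, he)
    bad <- bad[enp[bad] <= 0]
  }
  list(x = stats::rnorm(n, 0, enp), enp = enp)
}

#' Forward normal cloud generator
#'
#' For each drop, a second-order entropy `En' ~ N(En, He^2)` is drawn
#' (resampled until positive), the drop value `x ~ N(Ex, En'^2)`, and the
#' membership degree `mu = exp(-(x - Ex)^2 / (2 En'^2))`. With `He = 0`
#' this reduces to a plain Gaussian `N(Ex, En^2)`.
#'
#' @param params A [cloud_params()] object.
#' @param n Number of drops, >= 1.
#' @param seed Optional integer seed (global RNG state restored).
#' @return data.frame with columns `x`, `mu`, `en_prime`.
#' @export
normal_cloud_generator <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "cloud_params"), n >= 1L)
  with_seed_if(seed, {
    z <- cloud_noise(n, params$en, params$he)
    x <- params$ex + z$x
    mu <- exp(-(x - params$ex)^2 / (2 * z$enp^2))
    data.frame(x = x, mu = mu, en_prime = z$enp)
  })
}

#' Configuration of the cloud-model differential evolution
#'
#' @param pop_size Population size, >= 4 (DE needs three distinct donors
#'   plus the target).
#' @param generations Number of generations, >= 1.
#' @param f_scale Differential weight `F`, in `(0, 2]`.
#' @param cr Crossover probability, in `[0, 1]`.
#' @param en_init,en_final Entropy schedule of the cloud perturbation
#'   (pixels for contour displacements); decays geometrically across
#'   generations, `en_init >= en_final > 0`.
#' @param he_frac Hyper-entropy as a fraction of the current entropy.
#' @param smooth_window Odd circular moving-average window applied to the
#'   perturbation along the coordinate index (1 = independent drops).
#'   Correlated drops make coherent deformations of smoothness-coupled
#'   encodings such as contour displacements.
#' @param seed Integer RNG seed.
#' @return A list of class `de_config`.
#' @export
de_config <- function(pop_size = 30L, generations = 150L, f_scale = 0.5,
                      cr = 0.9, en_init = 3, en_final = 0.3,
                      he_frac = 0.1, smooth_window = 1L, seed = 1L) {
  if (pop_size < 4L) stop("pop_size must be >= 4", call. = FALSE)
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  if (f_scale <= 0 || f_scale > 2) stop("f_scale must be in (0, 2]",
                                        call. = FALSE)
  if (cr < 0 || cr > 1) stop("cr must be in [0, 1]", call. = FALSE)
  if (!(en_init >= en_final && en_final > 0)) {
    stop("need en_init >= en_final > 0", call. = FALSE)
  }
  if (he_frac < 0) stop("he_frac must be >= 0", call. = FALSE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 f_scale = f_scale, cr = cr, en_init = en_init,
                 en_final = en_final, he_frac = he_frac,
                 smooth_window = smooth_window,
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Entropy annealing schedule
#'
#' Geometric decay from `en_init` at stage 0 to `en_final` at the last
#' stage (`generations - 1`), so the schedule spends equal numbers of
#' generations per decade of entropy (a linear ramp would leave almost no
#' generations at fine perturbation scales).
#'
#' @param config A [de_config()] object.
#' @param stage 0-based generation index.
#' @return Entropy value for this stage.
#' @export
cloud_entropy_schedule <- function(config, stage) {
  gmax <- max(config$generations - 1L, 1L)
  frac <- clamp(stage / gmax, 0, 1)
  config$en_init * (config$en_final / config$en_init)^frac
}

# Circular moving average along the coordinate index, rescaled by
# sqrt(window) so the marginal perturbation scale is preserved.
smooth_circular <- function(x, window) {
  if (window <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / window, window),
                           circular = TRUE)) * sqrt(window)
}

#' One generation of cloud-model differential evolution
#'
#' For each target `i`: a classical DE/rand/1/bin trial
#' `t = a + F (b - c)` with distinct random donors and binomial crossover
#' (one forced coordinate), then every trial coordinate receives an
#' additive drop from the normal cloud generator with `Ex = 0`,
#' `En = En(stage)`, `He = he_frac * En`. Greedy selection keeps the better
#' of trial and target, so the best individual always survives unchanged.
#'
#' @param pop `pop_size x d` matrix of individuals.
#' @param fit Fitness vector (lower is better), one value per row of `pop`.
#' @param fn Fitness function for evaluating trial vectors.
#' @param config A [de_config()] object.
#' @param stage 0-based generation index (drives the entropy schedule).
#' @return List with updated `pop` and `fit`.
#' @export
cloud_de_generation <- function(pop, fit, fn, config, stage) {
  np <- nrow(pop)
  d <- ncol(pop)
  if (np < 4L) stop("pop_size must be >= 4", call. = FALSE)
  if (length(fit) != np) stop("fitness length must match population",
                              call. = FALSE)
  en <- cloud_entropy_schedule(config, stage)
  he <- config$he_frac * en
  newpop <- pop
  newfit <- fit
  for (i in seq_len(np)) {
    donors <- sample(seq_len(np)[-i], 3L)
    trial <- pop[donors[1L], ] +
      config$f_scale * (pop[donors[2L], ] - pop[donors[3L], ])
    jrand <- sample.int(d, 1L)
    cross <- stats::runif(d) < config$cr
    cross[jrand] <- TRUE
    trial[!cross] <- pop[i, !cross]
    trial <- trial + smooth_circular(cloud_noise(d, en, he)$x,
                                     config$smooth_window)
    ft <- fn(trial)
    if (ft < fit[i]) {
      newpop[i, ] <- trial
      newfit[i] <- ft
    }
  }
  list(pop = newpop, fit = newfit)
}

#' Run the cloud-model DE optimiser
#'
#' Minimises `fn` over `dim`-dimensional vectors.
#'
#' @param fn Fitness function (vector -> scalar, lower is better).
#' @param dim Problem dimension.
#' @param config A [de_config()] object; all randomness is governed by
#'   `config$seed`.
#' @param init Optional initial population: a `pop_size x dim` matrix, or
#'   a `function(pop_size, dim)` returning one (invoked inside the seeded
#'   RNG scope). Default: cloud drops of entropy `en_init` around zero,
#'   with the all-zero individual included as the first row.
#' @return List of class `cloud_de_result`: `best`, `best_fit`, `trace`
#'   (data.frame `generation,best_energy,mean_energy`), `pop`, `fit`.
#' @export
run_cloud_de <- function(fn, dim, config = de_config(), init = NULL) {
  with_seed_if(config$seed, {
    pop <- if (is.null(init)) {
      p <- matrix(cloud_noise(config$pop_size * dim, config$en_init,
                              config$he_frac * config$en_init)$x,
                  config$pop_size, dim)
      p[1L, ] <- 0
      p
    } else if (is.function(init)) {
      init(config$pop_size, dim)
    } else {
      stopifnot(nrow(init) == config$pop_size, ncol(init) == dim)
      init
    }
    fit <- apply(pop, 1L, fn)
    trace <- vector("list", config$generations)
    for (g in seq_len(config$generations) - 1L) {
      res <- cloud_de_generation(pop, fit, fn, config, g)
      pop <- res$pop
      fit <- res$fit
      trace[[g + 1L]] <- c(generation = g, best_energy = min(fit),
                           mean_energy = mean(fit))
    }
    best <- which.min(fit)
    structure(list(best = pop[best, ], best_fit = fit[best],
                   trace = as.data.frame(do.call(rbind, trace)),
                   pop = pop, fit = fit),
              class = "cloud_de_result")
  })
}

#' Refine a contour by cloud-model differential evolution
#'
#' Individuals encode per-point radial displacements along the initial
#' contour's outward normals (clamped to `max_disp` pixels), which keeps
#' candidate contours closed and ordered by construction. The fitness is
#' the discrete Snake energy of the displaced contour, so this is a global
#' refinement of the same objective that [evolve_snake()] descends
#' locally.
#'
#' Because neighbouring displacements are coupled by the smoothness terms,
#' the default configuration differs from the generic optimiser: full
#' mutant inheritance (`cr = 1`; coordinate-wise crossover would stitch
#' discontinuities into an otherwise smooth contour) and a cloud
#' perturbation smoothed along the contour (`smooth_window = 9`). The
#' initial population covers the encoding's dominant axis with uniform
#' inflate/deflate offsets plus smooth fields, and always contains the
#' zero-displacement individual, so the final energy never exceeds the
#' initial contour's.
#'
#' @param init Initial closed contour (typically the PCNN contour, possibly
#'   pre-evolved by a short Snake descent).
#' @param image Image matrix (used when `edge` is not supplied).
#' @param params A [snake_params()] object (energy weights).
#' @param config A [de_config()] object.
#' @param max_disp Displacement clamp in pixels.
#' @param edge Optional precomputed [edge_potential()].
#' @return A `segmentation_result` with an extra `de_trace` field.
#' @export
optimize_contour <- function(init, image, params = snake_params(),
                             config = de_config(cr = 1.0,
                                                smooth_window = 9L),
                             max_disp = 10, edge = NULL) {
  init <- as_contour(init)
  if (is.null(edge)) edge <- edge_potential(image, params$edge_sigma)
  h <- nrow(edge$potential)
  w <- ncol(edge$potential)
  base <- unclass(init)
  nrm <- contour_normals(init)
  n <- nrow(base)
  decode <- function(d) {
    d <- clamp(d, -max_disp, max_disp)
    pts <- base + d * nrm
    cbind(clamp(pts[, 1L], 0.5, h - 0.5), clamp(pts[, 2L], 0.5, w - 0.5))
  }
  fn <- function(d) {
    pts <- decode(d)
    internal_energy(pts, params$alpha, params$beta) +
      params$kappa * sum(bilinear_sample(edge$potential, pts))
  }
  init_pop <- function(np, d) {
    p <- t(vapply(seq_len(np), function(j) {
      stats::runif(1L, -max_disp, max_disp) +
        smooth_circular(cloud_noise(d, config$en_init,
                                    config$he_frac * config$en_init)$x,
                        max(config$smooth_window, 9L))
    }, numeric(d)))
    p[1L, ] <- 0
    p
  }
  res <- run_cloud_de(fn, n, config, init = init_pop)
  ct <- as_contour(decode(res$best))
  structure(list(contour = ct, mask = contour_to_mask(ct, c(h, w)),
                 trace = NULL, de_trace = res$trace, converged = TRUE,
                 iterations = config$generations, energy = res$best_fit),
            class = "segmentation_result")
}
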