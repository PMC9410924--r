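# Shared front end of both segmentation methods: denoise, build the PCNN
# stimulus (organs are dark in B-mode, so the stimulus is the inverted
# denoised image), run the PCNN, take the Otsu first-fire split, and
# extract the initial contour.
pipeline_front <- function(image, denoise = diffusion_params(),
                           pcnn = pcnn_params(), dark_object = TRUE,
                           edge_sigma = 2.0, min_area = 25L,
                           n_points = 100L) {
  den <- denoise_pm(image, denoise)
  stim <- clamp(den, 0, 1)
  if (dark_object) stim <- 1 - stim
  run <- run_pcnn(stim, pcnn)
  mask0 <- select_segment_iteration(run, criterion = "first_fire_otsu")
  ct0 <- extract_initial_contour(mask0, min_area = min_area,
                                 n_points = n_points)
  list(denoised = den, stimulus = stim, pcnn_run = run, pcnn_mask = mask0,
       initial_contour = ct0, edge = edge_potential(den, edge_sigma))
}

#' Segment an ultrasound-like image
#'
#' Full pipeline: Perona-Malik denoising, PCNN initial-contour extraction,
#' then either the classical Snake (`method = "snake"`) or the hybrid
#' cloud-model refinement (`method = "cloud-acm"`: a short Snake descent
#' followed by cloud-model differential evolution of the same Snake
#' energy).
#'
#' @param image Image matrix (intensities on `[0, 1]`).
#' @param method `"cloud-acm"` or `"snake"`.
#' @param dark_object The target region is darker than its surroundings
#'   (B-mode organ convention); the PCNN stimulus is inverted accordingly.
#' @param denoise,pcnn,snake,de Stage parameter objects.
#' @param pre_iters Snake iterations preceding the cloud refinement.
#' @param min_area Minimum PCNN component area (pixels).
#' @param seed Optional seed overriding `de$seed`.
#' @return A `segmentation_result` with extra fields `initial_contour`,
#'   `pcnn_mask`, `denoised`, `method`.
#' @export
segment_image <- function(image, method = c("cloud-acm", "snake"),
                          dark_object = TRUE,
                          denoise = diffusion_params(),
                          pcnn = pcnn_params(),
                          snake = snake_params(),
                          de = de_config(cr = 1.0, smooth_window = 9L),
                          pre_iters = 50L, min_area = 25L, seed = NULL) {
  method <- match.arg(method)
  validate_gray_image(image, "image")
  if (!is.null(seed)) de$seed <- as.integer(seed)
  front <- pipeline_front(image, denoise, pcnn, dark_object,
                          edge_sigma = snake$edge_sigma,
                          min_area = min_area)
  res <- if (method == "snake") {
    evolve_snake(front$initial_contour, image, snake, edge = front$edge)
  } else {
    presnake <- snake
    presnake$max_iter <- as.integer(pre_iters)
    pre <- evolve_snake(front$initial_contour, image, presnake,
                        edge = front$edge)
    optimize_contour(pre$contour, image, snake, de, edge = front$edge)
  }
  res$initial_contour <- front$initial_contour
  res$pcnn_mask <- front$pcnn_mask
  res$denoised <- front$denoised
  res$method <- method
  res
}

#' Paired phantom benchmark of both segmentation methods
#'
#' Generates one phantom per `(sigma, seed)` cell, runs the shared front
#' end (denoising + PCNN) once, and evolves both the classical Snake and
#' the cloud-model refinement from the identical initial contour, scoring
#' each against the known truth mask. Also scores the denoising stage by
#' PSNR/MSE against the clean image. The whole table is reproducible from
#' the seeds.
#'
#' @param sigmas Speckle scales of the phantom grid.
#' @param seeds Integer phantom seeds (one run per seed per sigma).
#' @param shape Phantom frame shape.
#' @param methods Subset of `c("snake", "cloud-acm")`.
#' @param denoise,pcnn,snake,de Stage parameter objects.
#' @param pre_iters Snake iterations preceding the cloud refinement.
#' @param phantom_args Extra arguments passed to [generate_phantom()]
#'   (e.g. `contrast`, `blur_sd`, `object`).
#' @param out_csv Optional path; the per-run table is written as CSV.
#' @return data.frame with one row per run x method: `sigma`, `seed`,
#'   `method`, `error_rate`, `dsc`, `mcc`, `psnr_noisy`, `psnr_denoised`,
#'   `mse_noisy`, `mse_denoised`.
#' @export
benchmark_suite <- function(sigmas = c(0.4, 0.8, 1.2), seeds = 1:10,
                            shape = c(96L, 96L),
                            methods = c("snake", "cloud-acm"),
                            denoise = diffusion_params(),
                            pcnn = pcnn_params(),
                            snake = snake_params(),
                            de = de_config(cr = 1.0, smooth_window = 9L),
                            pre_iters = 50L,
                            phantom_args = list(),
                            out_csv = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (s in sigmas) {
    for (sd in seeds) {
      ph <- do.call(generate_phantom,
                    c(list(shape = shape, sigma = s, seed = sd),
                      phantom_args))
      front <- pipeline_front(ph$noisy, denoise, pcnn,
                              edge_sigma = snake$edge_sigma)
      p_noisy <- psnr(ph$clean, ph$noisy)
      p_den <- psnr(ph$clean, front$denoised)
      m_noisy <- mse(ph$clean, ph$noisy)
      m_den <- mse(ph$clean, front$denoised)
      for (meth in methods) {
        res <- if (meth == "snake") {
          evolve_snake(front$initial_contour, front$denoised, snake,
                       edge = front$edge)
        } else {
          presnake <- snake
          presnake$max_iter <- as.integer(pre_iters)
          pre <- evolve_snake(front$initial_contour, front$denoised,
                              presnake, edge = front$edge)
          de_run <- de
          de_run$seed <- as.integer(sd)
          optimize_contour(pre$contour, front$denoised, snake, de_run,
                           edge = front$edge)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sigma = s, seed = sd, method = meth,
          error_rate = pixel_error_rate(res$mask, ph$truth_mask),
          dsc = dice_coefficient(res$mask, ph$truth_mask),
          mcc = matthews_cc(res$mask, ph$truth_mask),
          psnr_noisy = p_noisy, psnr_denoised = p_den,
          mse_noisy = m_noisy, mse_denoised = m_den,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(df, out_csv, row.names = FALSE)
  df
}

#' Aggregate a benchmark table
#'
#' Mean of every metric per method (over all sigma and seeds).
#'
#' @param df Output of [benchmark_suite()].
#' @return data.frame with one row per method.
#' @export
summarize_benchmark <- function(df) {
  agg <- aggregate(df[, c("error_rate", "dsc", "mcc", "psnr_noisy",
                          "psnr_denoised", "mse_noisy", "mse_denoised")],
                   by = list(method = df$method), FUN = mean)
  agg[order(agg$method), , drop = FALSE]
}
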