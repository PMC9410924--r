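test_that("the normal cloud generator has the stated moments and membership", {
  # He = 0 degenerates to a plain Gaussian N(Ex, En^2)
  drops <- normal_cloud_generator(cloud_params(ex = 2, en = 0.5, he = 0),
                                  n = 1e5, seed = 1)
  expect_true(all(drops$en_prime == 0.5))
  expect_equal(sd(drops$x), 0.5, tolerance = 0.02)
  ks <- suppressWarnings(ks.test(drops$x, "pnorm", 2, 0.5))
  expect_gt(ks$p.value, 0.01)

  # membership degree is the Gaussian kernel of the drop, 1 at the centre
  expect_equal(drops$mu,
               exp(-(drops$x - 2)^2 / (2 * drops$en_prime^2)))
  expect_equal(max(normal_cloud_generator(cloud_params(0, 1, 0.1), 1e4,
                                          seed = 2)$mu), 1,
               tolerance = 1e-3)

  # the canonical (Ex, En, He) = (0, 1, 0.04) cloud
  d2 <- normal_cloud_generator(cloud_params(0, 1, 0.04), n = 1e5, seed = 3)
  expect_equal(mean(d2$x), 0, tolerance = 0.02)
  expect_gte(mean(abs(d2$x) <= 3 * max(d2$en_prime)), 0.997)

  expect_error(cloud_params(en = 0), "en")
  expect_error(cloud_params(he = -1), "he")
})

test_that("the entropy schedule anneals geometrically between its endpoints", {
  cfg <- de_config(generations = 11, en_init = 3, en_final = 0.3)
  expect_equal(cloud_entropy_schedule(cfg, 0), 3)
  expect_equal(cloud_entropy_schedule(cfg, 10), 0.3)
  mid <- cloud_entropy_schedule(cfg, 5)
  expect_equal(mid, sqrt(3 * 0.3))
  expect_error(de_config(en_init = 0.1, en_final = 0.3), "en_init")
  expect_error(de_config(pop_size = 3), "pop_size")
})

test_that("cloud perturbation with vanishing entropy reduces to classical DE", {
  sphere <- function(x) sum(x^2)
  cfg <- de_config(pop_size = 8, generations = 1, en_init = 1e-14,
                   en_final = 1e-15, seed = 99)
  set.seed(99)
  pop <- matrix(rnorm(8 * 5), 8, 5)
  fit <- apply(pop, 1, sphere)

  # classical DE/rand/1/bin oracle consuming the identical RNG stream
  # (the cloud draws are made and then suppressed)
  set.seed(1234)
  res <- cloud_de_generation(pop, fit, sphere, cfg, stage = 0)
  set.seed(1234)
  newpop <- pop; newfit <- fit
  for (i in 1:8) {
    don <- sample((1:8)[-i], 3)
    tr <- pop[don[1], ] + cfg$f_scale * (pop[don[2], ] - pop[don[3], ])
    jr <- sample.int(5, 1)
    cross <- runif(5) < cfg$cr
    cross[jr] <- TRUE
    tr[!cross] <- pop[i, !cross]
    invisible(rnorm(5, cfg$en_init, cfg$he_frac * cfg$en_init))
    invisible(rnorm(5, 0, 1))   # suppressed cloud drops
    ft <- sphere(tr)
    if (ft < fit[i]) { newpop[i, ] <- tr; newfit[i] <- ft }
  }
  expect_equal(res$pop, newpop, tolerance = 1e-12)
})

test_that("best-so-far energy is non-increasing across generations", {
  rosen <- function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
  cfg <- de_config(pop_size = 12, generations = 40, en_init = 0.5,
                   en_final = 0.01, seed = 4)
  res <- run_cloud_de(rosen, 4, cfg,
                      init = function(np, d) matrix(runif(np * d, -2, 2), np, d))
  expect_true(all(diff(res$trace$best_energy) <= 0))
  expect_equal(res$best_fit, min(res$trace$best_energy))
})

test_that("the optimiser solves the sphere benchmark", {
  sphere <- function(x) sum(x^2)
  ok <- 0
  for (s in 1:10) {
    cfg <- de_config(pop_size = 30, generations = 200, en_init = 0.5,
                     en_final = 1e-4, seed = s)
    res <- run_cloud_de(sphere, 10, cfg,
                        init = function(np, d) matrix(runif(np * d, -5, 5), np, d))
    if (res$best_fit < 1e-3) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("contour refinement recovers a dilated initialisation", {
  ph <- generate_phantom(shape = c(96, 96),
                         object = phantom_object(c(96, 96),
                                                 semi_axes = c(20, 20),
                                                 indent = 0),
                         sigma = 0, blur_sd = 1.5)
  init <- circle_contour(c(48, 48), 25)   # 5 px outside the true edge
  opt <- optimize_contour(init, ph$clean, snake_params(),
                          de_config(cr = 1, smooth_window = 9, seed = 7))
  r <- sqrt(rowSums((unclass(opt$contour) - 48)^2))
  expect_lt(mean(abs(r - 20)), 1)

  # the zero-displacement individual bounds the final energy from above
  e0 <- snake_energy(init, ph$clean, snake_params())
  expect_lte(opt$energy, e0)
})

test_that("identical seeds give byte-identical refinement results", {
  ph <- quiet_phantom(sigma = 0.8, seed = 5, shape = c(64, 64))
  init <- extract_initial_contour(ph$truth_mask)
  cfg <- de_config(generations = 30, cr = 1, smooth_window = 9, seed = 3)
  a <- optimize_contour(init, ph$noisy, snake_params(), cfg)
  b <- optimize_contour(init, ph$noisy, snake_params(), cfg)
  expect_identical(a$mask, b$mask)
  expect_identical(a$contour, b$contour)
})
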