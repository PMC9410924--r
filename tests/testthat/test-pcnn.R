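test_that("uncoupled feeding recursion reduces to the stimulus", {
  # beta = 0, VF = 0, huge theta: nothing fires, F[1] = S exactly
  p <- pcnn_params(beta = 0, vf = 0, theta0 = 1e6)
  s <- matrix(runif(25), 5, 5)
  st <- pcnn_step(pcnn_init(dim(s), p), s, p)
  expect_equal(st$f, s)
  expect_true(all(st$y == 0))
  # second step: F[2] = decay_f * S + S
  st2 <- pcnn_step(st, s, p)
  expect_equal(st2$f, p$decay_f * s + s)
})

test_that("a single bright pixel fires once its activity beats the threshold", {
  p <- pcnn_params(beta = 0, vf = 0, theta0 = 0.5)
  s <- matrix(0, 7, 7)
  s[4, 4] <- 1
  st <- pcnn_step(pcnn_init(dim(s), p), s, p)
  expect_equal(st$y[4, 4], 1L)
  expect_equal(sum(st$y), 1)
  # threshold recharges by vtheta exactly where it fired
  expect_equal(st$theta[4, 4], p$decay_theta * 0.5 + p$vtheta)
  expect_equal(st$theta[1, 1], p$decay_theta * 0.5)
})

test_that("vectorized PCNN equals the per-pixel brute-force oracle", {
  set.seed(123)
  p <- pcnn_params(theta0 = 0.8, max_iter = 10)
  for (rep in 1:5) {
    img <- matrix(runif(16 * 16), 16, 16)
    oracle <- pcnn_brute_force(img, p, 10)
    st <- pcnn_init(dim(img), p)
    for (a in 1:10) {
      st <- pcnn_step(st, img, p)
      expect_identical(st$y, oracle[[a]])
    }
  }
})

test_that("run_pcnn firing schedule follows stimulus structure", {
  # constant image: all pixels first fire together
  run <- run_pcnn(matrix(0.5, 8, 8), pcnn_params(max_iter = 40))
  expect_equal(length(unique(as.integer(run$first_fire))), 1)

  # theta0 below all intensities: everything fires at a = 1
  run1 <- run_pcnn(matrix(runif(64, 0.5, 1), 8, 8),
                   pcnn_params(theta0 = 0.4))
  expect_true(all(run1$first_fire == 1L))

  # two-level image: classes fire at different iterations, synchronously
  # within each class up to kernel-coupled boundary pixels
  img <- matrix(0.7, 24, 24)
  img[8:16, 8:16] <- 0.3
  run2 <- run_pcnn(img, pcnn_params(max_iter = 60))
  interior_hi <- run2$first_fire[2:4, 2:4]
  interior_lo <- run2$first_fire[11:13, 11:13]
  expect_equal(length(unique(as.integer(interior_hi))), 1)
  expect_equal(length(unique(as.integer(interior_lo))), 1)
  expect_lt(interior_hi[1], interior_lo[1])
})

test_that("uncoupled firing order is monotone in the stimulus", {
  p <- pcnn_params(beta = 0, vf = 0, vl = 0, max_iter = 80)
  s <- matrix(runif(100, 0.05, 1), 10, 10)
  run <- run_pcnn(s, p)
  expect_true(run$all_fired)
  ord <- order(as.numeric(s))
  ff <- as.numeric(run$first_fire)[ord]
  expect_true(all(diff(ff) <= 0))  # higher stimulus never fires later
})

test_that("every positive pixel fires within the threshold-decay bound", {
  p <- pcnn_params(beta = 0, vf = 0, vl = 0, theta0 = 1, max_iter = 100)
  s <- matrix(runif(64, 0.1, 1), 8, 8)
  run <- run_pcnn(s, p)
  expect_true(run$all_fired)
  btheta <- -log(p$decay_theta)
  bound <- ceiling((log(p$theta0) - log(min(s))) / btheta) + 1
  expect_lte(max(run$first_fire), bound)
})

test_that("segmentation iteration selection maximises map entropy", {
  mk <- function(p) {
    m <- matrix(0L, 10, 10)
    m[seq_len(round(p * 100))] <- 1L
    m
  }
  run <- structure(list(fired = list(mk(0.02), mk(0.48), mk(0.97)),
                        first_fire = matrix(1L, 10, 10), n_iter = 3,
                        all_fired = TRUE),
                   class = "pcnn_run")
  sel <- select_segment_iteration(run)
  expect_equal(attr(sel, "iteration"), 2)
  expect_equal(mean(sel), 0.48)

  # single non-trivial candidate comes back unchanged
  run1 <- structure(list(fired = list(mk(0.3)),
                         first_fire = matrix(1L, 10, 10), n_iter = 1,
                         all_fired = TRUE),
                    class = "pcnn_run")
  expect_equal(mean(select_segment_iteration(run1)), 0.3)

  # all trivial maps: no segmentation
  run0 <- structure(list(fired = list(mk(0), mk(1)),
                         first_fire = matrix(1L, 10, 10), n_iter = 2,
                         all_fired = TRUE),
                    class = "pcnn_run")
  expect_error(select_segment_iteration(run0), "non-trivial")
})

test_that("PCNN isolates the organ on a noise-free phantom", {
  ph <- quiet_phantom(sigma = 0)
  stim <- 1 - ph$clean
  run <- run_pcnn(stim, pcnn_params())
  sel <- select_segment_iteration(run, criterion = "first_fire_otsu")
  expect_gte(dice_coefficient(matrix(as.integer(sel), nrow(sel)),
                              ph$truth_mask), 0.9)
})

test_that("initial contour extraction traces discs faithfully", {
  mask <- disc_mask(c(64, 64), c(32, 32), 20)
  ct <- extract_initial_contour(mask)
  expect_equal(nrow(ct), 100)
  r <- sqrt(rowSums((unclass(ct) - 32)^2))
  expect_true(all(abs(r - 20) < 1.5))
  # closed, non-degenerate, clockwise
  expect_gte(nrow(ct), 4)
  expect_gt(contour_area(ct, signed = TRUE), 0)
  # polygon area close to the pixel count
  expect_equal(contour_area(ct), sum(mask), tolerance = 0.05)

  # small companion component is discarded
  mask2 <- mask
  mask2[3:5, 3:5] <- 1L
  ct2 <- extract_initial_contour(mask2, min_area = 25)
  r2 <- sqrt(rowSums((unclass(ct2) - 32)^2))
  expect_true(all(abs(r2 - 20) < 1.5))

  # nothing large enough
  tiny <- matrix(0L, 32, 32)
  tiny[5:6, 5:6] <- 1L
  expect_error(extract_initial_contour(tiny, min_area = 25), "min_area")
})
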