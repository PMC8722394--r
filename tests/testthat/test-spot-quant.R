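test_that("flat and degenerate images are handled", {
  expect_warning(sp <- detect_spots(matrix(0, 40, 40)), "zero-variance")
  expect_identical(nrow(sp), 0L)
  expect_error(detect_spots(matrix(c(NA, 1:15), 4, 4)), "non-finite")
  expect_error(detect_spots(matrix(c(Inf, 1:15), 4, 4)), "non-finite")
})

test_that("rendered Gaussians are recovered at subpixel accuracy", {
  gy <- c(10.3, 25.7, 40.2, 15.8, 44.5)
  gx <- c(12.1, 30.4, 18.9, 48.6, 52.3)
  img <- render_gaussians_2d(60, 64, gy, gx, rep(200, 5), sigma = 1.5,
                             background = 10)
  sp <- detect_spots(img, det_params(sigma = 1.5, threshold = 50))
  spr <- sp[sp$retained, ]
  expect_identical(nrow(spr), 5L)
  m <- match_spots(spr$y, spr$x, gy, gx, tol = 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_true(all(m$errors <= 0.5))
  expect_true(all(abs(spr$amplitude - 200) / 200 < 0.02))
})

test_that("spots closer than the minimum separation merge to the brighter", {
  img <- render_gaussians_2d(30, 30, c(15, 15), c(14, 15), c(100, 100),
                             sigma = 1.5, background = 0)
  sp <- detect_spots(img, det_params(sigma = 1.5, threshold = 20,
                                     min_separation = 3,
                                     residual_threshold_factor = 100,
                                     min_unit_fraction = 0))
  expect_identical(nrow(sp[sp$retained, ]), 1L)
})

test_that("noise-free Gaussian fits recover the amplitude within 1%", {
  img <- render_gaussians_2d(31, 31, 15.6, 16.2, 100, sigma = 1.3,
                             background = 10)
  ft <- fit_amplitude(img, 16, 16)
  expect_true(ft$retained)
  expect_lt(abs(ft$amplitude - 100) / 100, 0.01)
  expect_lt(abs(ft$background - 10), 0.5)
  expect_lt(abs(ft$y - 15.6), 0.05)
  expect_lt(abs(ft$x - 16.2), 0.05)
  # free-sigma mode recovers the width too
  ftf <- fit_amplitude(img, 16, 16, sigma_fit = "free")
  expect_lt(abs(ftf$sigma - 1.3), 0.05)
})

test_that("Poisson-noise amplitudes are unbiased within 10% (Monte Carlo)", {
  base <- render_gaussians_2d(21, 21, 11, 11, 100, sigma = 1.3,
                              background = 10)
  set.seed(123)
  amps <- replicate(100, {
    noisy <- matrix(stats::rpois(length(base), base), nrow(base))
    fit_amplitude(noisy, 11, 11)$amplitude
  })
  expect_lt(abs(mean(amps) - 100) / 100, 0.10)
})

test_that("fit windows clipped by the image edge are flagged and excluded", {
  img <- render_gaussians_2d(30, 30, 3, 3, 100, sigma = 1.3, background = 5)
  ft <- fit_amplitude(img, 3, 3)
  expect_false(ft$retained)
  expect_identical(ft$flag, "edge")
  sp <- make_spot_set(c(100, 100, 100, 100, 100), retained = FALSE)
  expect_error(calibrate_unit(sp), "retained spots")
})

test_that("unit calibration averages the five dimmest spots", {
  sp <- make_spot_set(c(300, 95, 100, 105, 110, 90, 520))
  cal <- calibrate_unit(sp)
  expect_equal(cal$unit_amplitude, 100)
  expect_identical(cal$n_spots_used, 5L)
  cal_all_equal <- calibrate_unit(make_spot_set(rep(50, 8)))
  expect_equal(cal_all_equal$unit_amplitude, 50)
  expect_error(calibrate_unit(make_spot_set(c(90, 100, 110))), ">= 5")
  expect_warning(
    cal3 <- calibrate_unit(make_spot_set(c(90, 100, 110)), allow_fewer = TRUE),
    "only 3")
  expect_equal(cal3$unit_amplitude, 100)
})

test_that("mRNA counting divides by the unit, rounds, and floors at one", {
  sp <- make_spot_set(c(500, 100, 40, 260))
  cal <- calibrate_unit(make_spot_set(rep(100, 5)))
  out <- count_mrna(sp, cal)
  expect_identical(out$units, c(5L, 1L, 1L, 3L))
  bad <- cal; bad$unit_amplitude <- 0
  expect_error(count_mrna(sp, bad), "positive")
})

test_that("detection is equivariant under whole-pixel translations", {
  set.seed(21)
  gy <- runif(6, 20, 40); gx <- runif(6, 20, 40)
  img <- render_gaussians_2d(70, 70, gy, gx, rep(150, 6), 1.3, background = 10)
  img_shift <- render_gaussians_2d(70, 70, gy + 7, gx + 5, rep(150, 6), 1.3,
                                   background = 10)
  dp <- det_params(threshold = 40)
  a <- detect_spots(img, dp); a <- a[a$retained, ]
  b <- detect_spots(img_shift, dp); b <- b[b$retained, ]
  expect_identical(nrow(a), nrow(b))
  oa <- order(a$y, a$x); ob <- order(b$y, b$x)
  expect_equal(b$y[ob], a$y[oa] + 7, tolerance = 1e-3)
  expect_equal(b$x[ob], a$x[oa] + 5, tolerance = 1e-3)
})

test_that("raising the threshold never increases the retained count", {
  sc <- simulate_embryo(test_scene_params(seed = 9L))
  img <- max_project(sc$stack, "mRNA")
  counts <- vapply(c(30, 60, 120, 240, 480), function(thr) {
    sp <- detect_spots(img, det_params(threshold = thr))
    sum(sp$retained)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pipeline counts recover ground-truth totals on a small scene", {
  p <- test_scene_params(seed = 31L, n_spots_per_cell = 15L)
  sc <- simulate_embryo(p)
  img <- max_project(sc$stack, "mRNA")
  sp <- detect_spots(img)
  cal <- calibrate_unit(sp, zstack = sc$stack$voxels[1, , , ])
  expect_lt(abs(cal$unit_amplitude - p$unit_amplitude) / p$unit_amplitude,
            0.15)
  sp <- count_mrna(sp, cal)
  cc <- assign_spots(sp, sc$rois)
  relerr <- abs(cc$total - sc$truth$cells$total_units) /
    sc$truth$cells$total_units
  expect_lt(median(relerr), 0.15)
})
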