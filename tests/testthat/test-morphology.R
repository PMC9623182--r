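test_that("Otsu separates a perfectly bimodal input with pure classes", {
  v <- c(rep(10, 50), rep(200, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_true(all((v > thr) == (v == 200)))
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("Otsu equals the exhaustive 256-cut oracle on varied inputs", {
  set.seed(11)
  for (trial in 1:40) {
    v <- switch(1 + trial %% 4,
      rnorm(300),
      c(rnorm(200, -0.1, 0.03), rnorm(150, 0.3, 0.05)),
      runif(100, -1, 2),
      sample(0:255, 400, replace = TRUE))
    expect_equal(as.numeric(otsu_threshold(v)), otsu_oracle(v))
  }
})

test_that("Otsu misclassifies < 1% of a labelled two-Gaussian EXG mixture", {
  set.seed(99)
  n <- 1e4
  lab <- rbinom(n, 1, 0.5)
  v <- ifelse(lab == 1, rnorm(n, 0.3, 0.05), rnorm(n, -0.1, 0.03))
  thr <- otsu_threshold(v)
  expect_lt(mean((v > thr) != (lab == 1)), 0.01)
})

test_that("UAV segmentation recovers the truth mask exactly on noise-free scenes", {
  design <- generate_design(mini_config())
  truth <- sample_truth(design, "S1", seed = 21)
  sc <- render_scene(truth, seed = 5, params = render_params(dn_jitter = 0))
  m <- segment_vegetation_uav(sc$dom)
  expect_identical(m$values, sc$mask$values)
})

test_that("segmentation of a bare-soil scene is flagged", {
  design <- generate_design(mini_config())
  sc <- render_scene(empty_truth(design), seed = 5,
                     params = render_params(dn_jitter = 8))
  expect_warning(segment_vegetation_uav(sc$dom), "bimodality|near-empty")
})

test_that("segmentation stays >= 98% pixel-accurate at default DN noise", {
  design <- generate_design(mini_config(codes = c("T0", "T1"), layout_cols = 2L))
  truth <- sample_truth(design, "S1", seed = 13)
  sc <- render_scene(truth, seed = 31, params = render_params(dn_jitter = 8))
  m <- segment_vegetation_uav(sc$dom)
  expect_gt(mean(m$values == sc$mask$values), 0.98)
})

test_that("HSI conversion handles grey and primary colours", {
  g <- rgb_raster(matrix(c(128, 0, 0), 1, 3), matrix(c(128, 255, 0), 1, 3),
                  matrix(c(128, 0, 255), 1, 3))
  hsi <- rgb_to_hsi(g)
  expect_equal(hsi$saturation[1, 1], 0)
  expect_true(is.na(hsi$hue[1, 1]))
  expect_equal(hsi$intensity[1, 1], 128 / 255, tolerance = 1e-9)
  expect_equal(hsi$hue[1, 2], 120)
  expect_equal(hsi$saturation[1, 2], 1)
  expect_equal(hsi$hue[1, 3], 240)
})

test_that("VCEA recovers coverage on clean photos and ignores weed specks", {
  design <- generate_design(mini_config())
  truth <- sample_truth(design, "S1", seed = 17)
  p0 <- render_params(dn_jitter = 0, dsm_noise = 0)
  ph <- render_ground_photo(truth, "p01", seed = 4, params = p0)
  vm <- vcea_ground_mask(ph$photo, vcea_params(frame_px = ph$frame_px))
  d <- dim(vm$values); fp <- ph$frame_px
  n_int <- (d[1] - 2 * fp) * (d[2] - 2 * fp)
  cc <- sum(vm$values) / n_int
  expect_lt(abs(cc - ph$cc), 0.005)

  pw <- render_params(dn_jitter = 0, dsm_noise = 0, weeds = TRUE)
  ph2 <- render_ground_photo(truth, "p01", seed = 4, params = pw)
  vm2 <- vcea_ground_mask(ph2$photo, vcea_params(frame_px = ph2$frame_px))
  cc2 <- sum(vm2$values) / n_int
  expect_lt(abs(cc2 - cc), 0.005)
})

test_that("VCEA on an all-soil photo yields an empty mask with a warning", {
  design <- generate_design(mini_config())
  ph <- render_ground_photo(empty_truth(design), "p01", seed = 2,
                            params = render_params(dn_jitter = 0))
  expect_warning(vm <- vcea_ground_mask(ph$photo,
                                        vcea_params(frame_px = ph$frame_px)),
                 "no candidate")
  expect_true(all(vm$values == 0))
})

test_that("coverage_from_mask is the vegetation pixel fraction", {
  m1 <- raster_grid(matrix(1, 5, 5), units = "binary")
  m0 <- raster_grid(matrix(0, 5, 5), units = "binary")
  expect_equal(coverage_from_mask(m1), 1)
  expect_equal(coverage_from_mask(m0), 0)
  mm <- matrix(0, 4, 4); mm[1:2, ] <- 1
  expect_equal(coverage_from_mask(raster_grid(mm, units = "binary")), 0.5)
})

test_that("the canopy height model subtracts and clamps", {
  tr <- c(0.5, 1, 9.5, -1)
  bare <- raster_grid(matrix(36.15, 10, 10), tr, units = "m")
  stage <- raster_grid(matrix(36.45, 10, 10), tr, units = "m")
  expect_true(all(abs(canopy_height_model(stage, bare)$values - 0.30) < 1e-12))
  expect_true(all(canopy_height_model(bare, bare)$values == 0))
  below <- raster_grid(matrix(36.13, 10, 10), tr, units = "m")
  expect_true(all(canopy_height_model(below, bare)$values == 0))
  other <- raster_grid(matrix(36, 10, 10), c(0.5, 1, 19.5, -1), units = "m")
  expect_error(canopy_height_model(other, bare), "transform")
  small <- raster_grid(matrix(36, 5, 5), tr, units = "m")
  expect_error(canopy_height_model(small, bare), "shape")
})

test_that("plot height averages masked CHM pixels in centimetres", {
  tr <- c(0.5, 1, 19.5, -1)
  chm <- raster_grid(matrix(0.30, 20, 20), tr, units = "m")
  ring <- cbind(c(2, 12, 12, 2, 2), c(3, 3, 13, 13, 3))
  mask <- raster_grid(matrix(1, 20, 20), tr, units = "binary")
  expect_equal(plot_height(chm, ring, mask), 30)
  # empty mask falls back to the all-pixel mean with a warning
  mask0 <- raster_grid(matrix(0, 20, 20), tr, units = "binary")
  expect_warning(h <- plot_height(chm, ring, mask0), "empty")
  expect_equal(h, 30)
  # p90 statistic
  chm$values[1:10, ] <- 1
  expect_equal(plot_height(chm, ring, NULL, stat = "p90"),
               100 * quantile(chm$values[rasterize_plot(ring, chm)], 0.9,
                              names = FALSE))
})

test_that("canopy volume is the coverage-weighted height", {
  expect_equal(canopy_volume(0.5, 30), 15)
  expect_equal(canopy_volume(1, 27.3), 27.3)
  expect_equal(canopy_volume(0, 40), 0)
  expect_error(canopy_volume(1.2, 10), "CC")
  expect_error(canopy_volume(0.5, -1), "H")
})

test_that("late-season senescence degrades coverage recovery", {
  # the same trial rendered at S1 and S3 with default noise: yellowed
  # pixels sit near the segmentation threshold, so S3 coverage errors
  # must exceed S1 errors on average
  design <- generate_design(mini_config(codes = c("T0", "T1"), layout_cols = 2L))
  err <- function(stage, seed) {
    truth <- sample_truth(design, stage, seed = seed)
    sc <- render_scene(truth, seed = seed + 1000)
    m <- segment_vegetation_uav(sc$dom)
    cc <- vapply(seq_len(2), function(i)
      coverage_from_mask(m, rasterize_plot(design$polygons[[i]], m)), numeric(1))
    mean(abs(cc - sc$truth$plots$true_CC))
  }
  e1 <- mean(vapply(1:6, function(s) err("S1", s), numeric(1)))
  e3 <- mean(vapply(1:6, function(s) err("S3", s), numeric(1)))
  expect_gt(e3, e1)
})
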