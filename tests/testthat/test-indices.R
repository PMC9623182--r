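test_that("chromaticity normalisation handles equal, pure and black pixels", {
  g <- rgb_raster(matrix(c(100, 0, 0), 1, 3), matrix(c(100, 255, 0), 1, 3),
                  matrix(c(100, 0, 0), 1, 3))
  ch <- normalize_chromaticity(g)
  expect_equal(c(ch$r[1, 1], ch$g[1, 1], ch$b[1, 1]), rep(1 / 3, 3))
  expect_equal(c(ch$r[1, 2], ch$g[1, 2], ch$b[1, 2]), c(0, 1, 0))
  expect_false(ch$valid[1, 3])
  expect_true(is.na(ch$r[1, 3]))   # flagged, not NaN
  ok <- ch$valid
  expect_true(all(abs((ch$r + ch$g + ch$b)[ok] - 1) < 1e-9))
})

test_that("index formulas match hand evaluation", {
  # DN proportional to the chromaticities under test
  px <- function(r, g, b) flat_rgb(round(c(r, g, b) * 200), 1, 1)
  val <- function(name, r, g, b) {
    # use exact DN ratios: scale by 100 to keep integers
    dn <- c(r, g, b) * 100
    compute_index(name, flat_rgb(dn, 1, 1))$values[1, 1]
  }
  expect_equal(val("VARI", 0.2, 0.5, 0.3), 0.75)
  expect_equal(val("NDI", 0.5, 0.3, 0.2), (0.5 - 0.3) / (0.5 + 0.3 + 0.01))
  expect_equal(val("GLA", 0.2, 0.5, 0.3), 1.1 / 1.5)
  expect_equal(val("GLI", 0.2, 0.5, 0.3), 0.5 / 1.5)
  expect_equal(val("GRRI", 0.2, 0.5, 0.3), 0.4)
  expect_equal(val("GRVI", 0.3, 0.3, 0.4), 0)        # g = r symmetry
  expect_equal(val("EXG", 1, 1, 1), 0)               # grey pixel
  # raw-band indices return the DN itself
  expect_equal(compute_index("G", flat_rgb(c(10, 200, 30), 1, 1))$values[1, 1], 200)
  expect_error(compute_index("NDVI", flat_rgb(c(1, 1, 1))), "unknown")
})

test_that("denominator-zero pixels are flagged invalid", {
  # VARI: g + r - b = 0 at (0.25, 0.25, 0.5)
  g <- flat_rgb(c(50, 50, 100), 1, 1)
  expect_true(is.na(compute_index("VARI", g)$values[1, 1]))
  # GRRI at g = 0
  expect_true(is.na(compute_index("GRRI", flat_rgb(c(100, 0, 50), 1, 1))$values[1, 1]))
  # black pixel invalid for all chromaticity indices
  expect_true(is.na(compute_index("EXG", flat_rgb(c(0, 0, 0), 1, 1))$values[1, 1]))
})

test_that("index bounds and invariances hold on random DN rasters", {
  set.seed(7)
  for (trial in 1:5) {
    a <- array(sample(1:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
    g <- raster_grid(a, units = "DN8")
    grvi <- compute_index("GRVI", g)$values
    gli <- compute_index("GLI", g)$values
    ndi <- compute_index("NDI", g)$values
    exg <- compute_index("EXG", g)$values
    expect_true(all(abs(grvi) <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(abs(gli) <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(ndi >= -1 - 1e-12 & ndi <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(exg >= -1 - 1e-12 & exg <= 2 + 1e-12, na.rm = TRUE))
    # antisymmetry of the NDI and GRVI numerators
    expect_true(all(sign(ndi * grvi) <= 0, na.rm = TRUE))
    # brightness invariance: doubling DN leaves chromaticity indices alone
    # (scale within 8-bit range by halving instead)
    h <- raster_grid(a %/% 2 * 2, units = "DN8")
    g2 <- raster_grid((a %/% 2), units = "DN8")
    expect_equal(compute_index("GRVI", h)$values,
                 compute_index("GRVI", g2)$values, tolerance = 1e-12)
  }
})

test_that("raising the green share raises EXG, GRVI and GLI", {
  lo <- flat_rgb(c(80, 90, 60), 1, 1)
  hi <- flat_rgb(c(80, 140, 60), 1, 1)
  for (nm in c("EXG", "GRVI", "GLI"))
    expect_gt(compute_index(nm, hi)$values[1, 1],
              compute_index(nm, lo)$values[1, 1])
})

test_that("plot index means match the brute-force zonal oracle", {
  design <- generate_design(mini_config(codes = c("T0", "T1"), layout_cols = 2L))
  set.seed(3)
  nr <- 140; nc <- 320
  a <- array(sample(0:255, nr * nc * 3, replace = TRUE), c(nr, nc, 3))
  g <- raster_grid(a, c(0.025, 0.05, nr * 0.05 - 0.025, -0.05), units = "DN8")
  idx <- compute_index("GRVI", g)
  pm <- plot_index_means(idx, design)
  for (i in seq_len(nrow(pm))) {
    px <- rasterize_plot(design$polygons[[pm$plot_id[i]]], idx)
    vals <- idx$values[px]
    vals <- vals[is.finite(vals)]
    expect_equal(pm$mean[i], sum(vals) / length(vals))
    expect_identical(pm$valid_px[i], length(vals))
  }
  # constant raster -> every plot mean is the constant
  cg <- raster_grid(matrix(0.42, nr, nc), g$transform)
  expect_true(all(plot_index_means(cg, design)$mean == 0.42))
})

test_that("masked plot means use only vegetation pixels", {
  design <- generate_design(mini_config())
  tr <- design$polygons[[1]]
  g <- raster_grid(matrix(1, 140, 170), c(0.025, 0.05, 6.975, -0.05))
  m <- raster_grid(matrix(0, 140, 170), g$transform, units = "binary")
  px <- rasterize_plot(tr, g)
  half <- px[seq_len(nrow(px) %/% 2), ]
  m$values[half] <- 1
  g$values[half] <- 2
  pm <- plot_index_means(g, design, mask = m)
  expect_equal(pm$mean[1], 2)
  pm2 <- plot_index_means(g, design)
  expect_equal(pm2$mean[1], mean(g$values[px]))
})
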