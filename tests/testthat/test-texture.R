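test_that("quantization bins linearly with a clipped top edge", {
  q <- quantize(matrix(c(0, 0.26, 0.99, 1), 2, 2), n_levels = 4,
                value_range = c(0, 1))
  expect_equal(as.vector(q), c(0, 1, 3, 3))
  expect_warning(qc <- quantize(matrix(5, 3, 3), n_levels = 8), "constant")
  expect_true(all(qc == 0))
  m <- matrix(c(-1, 0.5, 2, NA), 2, 2)
  q2 <- quantize(m, n_levels = 4, value_range = c(0, 1))
  expect_equal(q2[1, 1], 0)          # below range clipped
  expect_equal(q2[1, 2], 3)          # above range clipped
  expect_true(is.na(q2[2, 2]))       # nodata preserved
})

test_that("glcm counts pairs, symmetrises and normalises", {
  g <- glcm(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  gc <- glcm(matrix(3, 3, 3), n_levels = 4)
  expect_equal(gc$p[4, 4], 1)
  expect_equal(sum(gc$p), 1)
  set.seed(2)
  for (k in 1:10) {
    w <- matrix(sample(0:5, 36, TRUE), 6, 6)
    g <- glcm(w, offsets = list(c(0L, 1L), c(1L, 0L)), n_levels = 6)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, t(g$p))
    expect_equal(g$p, brute_glcm(w, offsets = list(c(0L, 1L), c(1L, 0L)),
                                 n_levels = 6), tolerance = 1e-12)
  }
  expect_error(glcm(matrix(0, 1, 1)), "no valid pixel pair")
})

test_that("haralick features on degenerate and hand-worked matrices", {
  const <- suppressWarnings(haralick_features(glcm(matrix(2, 4, 4), n_levels = 4)))
  expect_equal(const[["energy"]], 1)
  expect_equal(const[["entropy"]], 0)
  expect_equal(const[["inertia"]], 0)
  expect_equal(const[["inverse_difference_moment"]], 1)
  expect_equal(const[["cluster_shade"]], 0)
  expect_equal(const[["cluster_prominence"]], 0)

  chk <- suppressWarnings(
    haralick_features(glcm(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))))
  expect_equal(chk[["energy"]], 0.5)
  expect_equal(chk[["entropy"]], 1)
  expect_equal(chk[["inertia"]], 1)
  expect_equal(chk[["inverse_difference_moment"]], 0.5)
  expect_equal(chk[["correlation"]], -1)

  # the f3 variant of Haralick correlation collapses onto correlation
  p <- brute_glcm(matrix(sample(0:3, 25, TRUE), 5, 5), n_levels = 4)
  f <- haralick_features(p, hc_variant = "f3")
  expect_equal(f[["haralick_correlation"]], f[["correlation"]])
})

test_that("all 8 features match the brute-force double-sum oracle", {
  set.seed(14)
  for (k in 1:25) {
    w <- matrix(sample(0:7, 36, TRUE), 6, 6)
    g <- glcm(w, n_levels = 8)
    expect_equal(haralick_features(g), brute_haralick(g$p),
                 tolerance = 1e-10)
  }
})

test_that("texture images equal per-window GLCM features, truncating at edges", {
  set.seed(31)
  m <- matrix(sample(0:7, 18 * 13, TRUE), 18, 13)
  m[sample(length(m), 12)] <- NA
  ti <- texture_image(raster_grid(m, cell = 1), radius = 2, n_levels = 8,
                      quantized = TRUE)
  for (r in c(1, 2, 7, 18)) for (c in c(1, 6, 13)) {
    if (is.na(m[r, c])) next
    rs <- max(1, r - 2):min(18, r + 2)
    cs <- max(1, c - 2):min(13, c + 2)
    p <- brute_glcm(m[rs, cs, drop = FALSE], n_levels = 8)
    expected <- brute_haralick(p)
    got <- vapply(ti, function(f) f$values[r, c], numeric(1))
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("constant rasters give unit energy and geometry passes through", {
  r <- raster_grid(matrix(0.5, 8, 6), x0 = 3, y0 = 7, cell = 0.045)
  ti <- suppressWarnings(texture_image(r, radius = 2, n_levels = 8))
  expect_true(all(ti$energy$values == 1))
  expect_true(all(ti$entropy$values == 0))
  expect_equal(ti$energy$x0, 3)
  expect_equal(ti$energy$y0, 7)
  expect_equal(ti$energy$cell, 0.045)
  expect_equal(dim(ti$inertia$values), c(8, 6))
  expect_error(texture_image(matrix(1, 1, 1)), "smaller than 2x2")
})

test_that("white noise carries more window entropy than a smoothed copy", {
  set.seed(77)
  w <- matrix(runif(40 * 40), 40, 40)
  sm <- (w[-1, -1] + w[-40, -1] + w[-1, -40] + w[-40, -40]) / 4  # 39x39 smooth
  e_noise <- texture_image(raster_grid(w, cell = 1), radius = 2, n_levels = 8)
  e_smooth <- texture_image(raster_grid(sm, cell = 1), radius = 2, n_levels = 8)
  expect_gt(mean(e_noise$entropy$values), mean(e_smooth$entropy$values))
})

test_that("plot texture means average masked feature pixels", {
  poly <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  f1 <- raster_grid(matrix(1, 10, 10), cell = 0.1)
  half <- matrix(0.2, 10, 10); half[6:10, ] <- 0.6
  f2 <- raster_grid(half, cell = 0.1)
  tm <- plot_texture_means(list(energy = f1, entropy = f2), poly,
                           excluded_strip_m = 0)
  expect_equal(tm[["energy"]], 1)
  expect_equal(tm[["entropy"]], 0.4)
  set.seed(4)
  m <- matrix(runif(100), 10, 10); m[sample(100, 7)] <- NA
  fr <- raster_grid(m, cell = 0.1)
  expect_equal(plot_texture_means(list(a = fr), poly, 0.25)[["a"]],
               brute_zonal_mean(fr, poly, strip = 0.25), tolerance = 1e-12)
})
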