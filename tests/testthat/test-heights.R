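test_that("rasterize_surface aggregates z-values per half-open cell", {
  cl <- data.frame(x = c(0.01, 0.02), y = c(0.01, 0.03), z = c(1, 3))
  rmax <- rasterize_surface(cl, x0 = 0, y0 = 0, cell = 0.05,
                            nrow = 1, ncol = 1, aggregator = "max")
  expect_equal(rmax$values[1, 1], 3)
  rmean <- rasterize_surface(cl, x0 = 0, y0 = 0, cell = 0.05,
                             nrow = 1, ncol = 1, aggregator = "mean")
  expect_equal(rmean$values[1, 1], 2)
  expect_error(rasterize_surface(data.frame(x = numeric(), y = numeric(),
                                            z = numeric())),
               "at least one point")
})

test_that("dense uniform points cover every cell; cell assignment matches a brute-force count", {
  set.seed(5)
  cl <- data.frame(x = runif(1000, 0, 0.1), y = runif(1000, 0, 0.1),
                   z = rnorm(1000))
  r <- rasterize_surface(cl, x0 = 0, y0 = 0, cell = 0.05, nrow = 2, ncol = 2,
                         aggregator = "max")
  expect_equal(sum(is.na(r$values)), 0)
  # brute-force per-cell max
  for (i in 1:2) for (j in 1:2) {
    sel <- cl$x >= (j - 1) * 0.05 & cl$x < j * 0.05 &
           cl$y >= (i - 1) * 0.05 & cl$y < i * 0.05
    expect_equal(r$values[i, j], max(cl$z[sel]))
  }
})

test_that("max-aggregated surface dominates the mean-aggregated one cellwise", {
  set.seed(8)
  cl <- data.frame(x = runif(400), y = runif(400), z = rnorm(400))
  rmax <- rasterize_surface(cl, x0 = 0, y0 = 0, cell = 0.2, nrow = 5, ncol = 5,
                            aggregator = "max")
  rmean <- rasterize_surface(cl, x0 = 0, y0 = 0, cell = 0.2, nrow = 5, ncol = 5,
                             aggregator = "mean")
  expect_true(all(rmax$values >= rmean$values, na.rm = TRUE))
})

test_that("crop surface height is the clamped DSM - DEM difference", {
  dsm <- raster_grid(matrix(c(1.2, 0.4, NA, 0.5), 2, 2), cell = 0.05)
  dem <- raster_grid(matrix(0.5, 2, 2), cell = 0.05)
  csh <- compute_csh(dsm, dem)
  expect_equal(csh$values[1, 1], 0.7)
  expect_equal(csh$values[2, 1], 0)          # negative clamped
  expect_true(is.na(csh$values[1, 2]))       # nodata propagates
  expect_equal(attr(csh, "n_clamped"), 1)
  expect_equal(compute_csh(dem, dem)$values, matrix(0, 2, 2))
  shifted <- raster_grid(matrix(0.5, 2, 2), x0 = 1, cell = 0.05)
  expect_error(compute_csh(dsm, shifted), "grids differ")
})

test_that("canopy height relief follows its definition and degenerate rule", {
  expect_equal(canopy_height_relief(c(0, 1, 2)), 0.5)
  expect_equal(canopy_height_relief(c(0.7, 0.7, 0.7)), 0)
  expect_equal(canopy_height_relief(c(0, 0, 0, 1)), 0.25)
  expect_error(canopy_height_relief(1), ">= 2 values")
})

make_csh_raster <- function(v) {
  n <- ceiling(sqrt(length(v)))
  m <- matrix(NA_real_, n, n)
  m[seq_along(v)] <- v
  raster_grid(m, x0 = 0, y0 = 0, cell = 1)
}
full_poly <- function(n) cbind(x = c(0, n, n, 0), y = c(0, 0, n, n))

test_that("plot metrics match hand-computed values on {0, 1, 2}", {
  r <- make_csh_raster(c(0, 1, 2))
  met <- plot_csh_metrics(r, full_poly(2), excluded_strip_m = 0)
  expect_equal(met[["mean"]], 1)
  expect_equal(met[["median"]], 1)
  expect_equal(met[["sd"]], 1)
  expect_equal(met[["range"]], 2)
  expect_equal(met[["relief"]], 0.5)
  expect_equal(met[["variance"]], met[["sd"]]^2)
})

test_that("degenerate flat canopy yields zero spread metrics with a warning", {
  r <- make_csh_raster(rep(0.7, 4))
  expect_warning(met <- plot_csh_metrics(r, full_poly(2), excluded_strip_m = 0),
                 "flat canopy")
  expect_equal(unname(met[c("mean", "min", "max", "median", "mode")]),
               rep(0.7, 5))
  expect_equal(unname(met[c("variance", "relief", "skewness", "kurtosis")]),
               rep(0, 4))
})

test_that("a single outlier lifts the upper percentiles and skews right", {
  r <- make_csh_raster(c(0, 0, 0, 10))
  met <- plot_csh_metrics(r, full_poly(2), excluded_strip_m = 0)
  expect_gt(met[["p95"]], met[["p75"]])
  expect_gt(met[["skewness"]], 0)
})

test_that("metrics agree with a brute-force oracle and obey shift invariance", {
  set.seed(42)
  for (n in c(17, 400, 3000)) {
    v <- rgamma(n, 2, 4)
    r <- make_csh_raster(v)
    met <- plot_csh_metrics(r, full_poly(ceiling(sqrt(n))),
                            excluded_strip_m = 0)
    oracle <- brute_csh_metrics(v)
    expect_equal(met[names(oracle)], oracle, tolerance = 1e-9)

    # permuting cell positions leaves metrics unchanged
    met_p <- plot_csh_metrics(make_csh_raster(sample(v)),
                              full_poly(ceiling(sqrt(n))),
                              excluded_strip_m = 0)
    expect_equal(met_p[names(oracle)], oracle, tolerance = 1e-9)

    # adding a constant shifts location metrics, leaves shape metrics
    k <- 0.37
    met_k <- plot_csh_metrics(make_csh_raster(v + k),
                              full_poly(ceiling(sqrt(n))),
                              excluded_strip_m = 0)
    loc <- c("mean", "min", "max", "median", "p25", "p75", "p90", "p95")
    expect_equal(met_k[loc], met[loc] + k, tolerance = 1e-9)
    shape <- c("variance", "sd", "range", "relief", "skewness", "kurtosis")
    expect_equal(met_k[shape], met[shape], tolerance = 1e-8)
  }
})

test_that("the excluded strip removes the plot entrance from the metrics", {
  m <- matrix(0, 4, 2)
  m[1:2, ] <- 5        # rows with centres at y = 0.5, 1.5 (the entrance)
  r <- raster_grid(m, x0 = 0, y0 = 0, cell = 1)
  poly <- cbind(x = c(0, 2, 2, 0), y = c(0, 0, 4, 4))
  met <- suppressWarnings(plot_csh_metrics(r, poly, excluded_strip_m = 2))
  expect_equal(met[["max"]], 0)
  expect_error(plot_csh_metrics(r, poly, excluded_strip_m = 3.6),
               "fewer than 2")
})
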