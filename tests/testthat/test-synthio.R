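test_that("design arithmetic: one replicate, one year, one harvest", {
  cfg <- sim_config(seed = 2, n_replicates = 1, years = default_years()[1],
                    harvests_per_year = 1, exclusions = "none")
  sc <- simulate_experiment(cfg, generate_clouds = FALSE,
                            generate_rasters = FALSE)
  expect_equal(nrow(sc$truth), 6)
  expect_equal(sort(unique(sc$truth$treatment)),
               sort(names(default_treatments())))
})

test_that("the same seed reproduces the truth table byte for byte", {
  cfg <- sim_config(seed = 123)
  a <- simulate_experiment(cfg, generate_clouds = FALSE, generate_rasters = FALSE)
  b <- simulate_experiment(cfg, generate_clouds = FALSE, generate_rasters = FALSE)
  expect_identical(a$truth, b$truth)
  expect_identical(a$polygons, b$polygons)
})

test_that("truth records obey the agronomic identities", {
  tr <- default_truth()
  expect_true(all(tr$FM_t_ha >= tr$DM_t_ha))
  expect_true(all(tr$DM_t_ha >= 0))
  expect_equal(tr$N_amount_kg_ha, tr$DM_t_ha * 10 * tr$N_conc_pct,
               tolerance = 1e-9)
  expect_true(all(tr$legume_prop >= 0 & tr$legume_prop <= 1))
  expect_true(all(tr$legume_prop[tr$treatment %in% c("G_CG", "G_LG")] == 0))
  expect_true(all(tr$legume_prop[tr$treatment %in% c("L_CG", "L_LG")] == 1))
})

test_that("config validation rejects impossible grids and budgets", {
  expect_error(sim_config(csh_cell_m = 2), "smaller than the plot")
  expect_error(sim_config(point_density = 0), "positive")
  expect_error(sim_config(harvests_per_year = 0), "at least 1")
  expect_error(sim_config(cell_budget = 1000), "cell budget")
})

test_that("a bare plot yields a cloud flat on the terrain", {
  spec <- treatment_spec("G_CG", 0, base_height = 0, base_FM = 0.1,
                         dm_content = 0.2)
  fp <- list(xmin = 0, xmax = 1.5, ymin = 0, ymax = 12)
  cl <- simulate_plot_cloud(spec, fp, density = 500, seed = 4)
  resid <- cl$z - (227 + 0.004 * cl$x + 0.002 * cl$y)
  expect_lt(max(abs(resid)), 0.02)   # only measurement noise remains
})

test_that("halving the climate multiplier halves the mean canopy height", {
  spec <- default_treatments()$CG
  fp <- list(xmin = 0, xmax = 1.5, ymin = 0, ymax = 12)
  h <- function(mult) {
    cl <- simulate_plot_cloud(spec, fp, climate_mult = mult, density = 2000,
                              seed = 99, cover = 1)
    mean(cl$z - (227 + 0.004 * cl$x + 0.002 * cl$y))
  }
  expect_equal(h(0.5) / h(1.0), 0.5, tolerance = 0.02)
  expect_equal(h(1.0), spec$base_height, tolerance = 0.05)
})

test_that("point counts follow the requested density", {
  spec <- default_treatments()$CG
  fp <- list(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  n <- nrow(simulate_plot_cloud(spec, fp, density = 2000, seed = 5))
  expect_lt(abs(n - 2000), 4 * sqrt(2000))  # Poisson tolerance
})

test_that("NIR rises with dry matter and zero noise freezes the bands", {
  cfg <- sim_config(seed = 6, n_replicates = 1, years = default_years()[2],
                    harvests_per_year = 1, exclusions = "none")
  sc <- simulate_experiment(cfg, generate_clouds = FALSE)
  tr <- sc$truth
  bands <- sc$bands[[1]]
  m <- vapply(seq_len(nrow(tr)), function(k) {
    p <- sc$polygons[sc$polygons$plot_id == tr$plot_id[k], ]
    zonal_band_means(bands, p, excluded_strip_m = 0)[c("nir", "red")]
  }, numeric(2))
  ord <- order(tr$DM_t_ha)
  expect_true(all(diff(m["nir", ord]) > 0))
  expect_true(all(diff(m["red", ord]) < 0))

  cfg0 <- sim_config(seed = 6, n_replicates = 1, years = default_years()[2],
                     harvests_per_year = 1, exclusions = "none",
                     reflectance_sd = 0)
  sc0 <- simulate_experiment(cfg0, generate_clouds = FALSE)
  p1 <- sc0$polygons[1, ]
  crop <- rg_crop(sc0$bands[[1]]$nir, p1$xmin, p1$xmax, p1$ymin, p1$ymax)
  expect_equal(var(as.vector(crop$values)), 0, tolerance = 1e-20)
  ti <- suppressWarnings(texture_image(crop, radius = 2, n_levels = 8))
  expect_true(all(ti$energy$values == 1))
})

test_that("short correlation lengths push texture toward white-noise entropy", {
  set.seed(10)
  f_long <- gaussian_random_field(60, 60, 0.05, 0.5)
  set.seed(10)
  f_short <- gaussian_random_field(60, 60, 0.05, 0)
  e <- function(f) {
    ti <- texture_image(raster_grid(f, cell = 0.05), radius = 2, n_levels = 8,
                        value_range = range(f))
    mean(ti$entropy$values)
  }
  expect_gt(e(f_short), e(f_long))
})

test_that("annual truth sums stay inside the observed field envelopes", {
  tr <- default_truth()
  ann <- annual_totals(tr)
  ann <- ann[ann$n_harvests == 3, ]
  expect_gte(min(ann$FM_t_ha), 10.36)
  expect_lte(max(ann$FM_t_ha), 103.94)
  nf <- nfix_table(tr)
  expect_true(all(nf$NFix_kg_ha > 0))
  key <- c("plot_id", "year", "harvest")
  af <- annual_totals(merge(tr, nf[, c(key, "NFix_kg_ha")], by = key))
  af <- af[af$n_harvests == 3, ]
  expect_gte(min(af$NFix_kg_ha), 59.73)
  expect_lte(max(af$NFix_kg_ha), 369.24)
})

test_that("scene export writes the plain-text bundle", {
  sc <- small_scene()
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  tr <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(tr), nrow(sc$truth))
  expect_equal(tr$FM_t_ha, sc$truth$FM_t_ha, tolerance = 1e-9)
  polys <- read_plots_geojson(file.path(dir, "plots.geojson"))
  expect_equal(nrow(polys), 12)
  cl <- read_xyz(list.files(file.path(dir, "clouds"), full.names = TRUE)[1])
  expect_true(all(c("x", "y", "z") %in% names(cl)))
})
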