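#' Treatment specification for the synthetic experiment
#'
#' One of the six sward treatments: two legume-grass mixtures (CG
#' clover-grass, LG lucerne-grass) and, for each, the pure legume (L_CG,
#' L_LG) and pure grass (G_CG, G_LG) stands.  `base_FM` and `base_height`
#' are per-harvest means under a neutral climate; `heterogeneity` and
#' `texture_correlation_length_m` shape the within-plot spatial structure
#' (mixtures are more heterogeneous than pure stands).
#'
#' @param label treatment label.
#' @param legume_proportion fraction of legumes in the sward, 0-1.
#' @param base_height mean canopy height per harvest, m.
#' @param base_FM fresh matter per harvest, t ha^-1.
#' @param dm_content dry matter fraction of fresh matter.
#' @param n_conc_legume,n_conc_grass N concentration, % of DM.
#' @param heterogeneity relative amplitude of the within-plot height field.
#' @param texture_correlation_length_m correlation length of the spatial
#'   noise fields, m.
#' @return a `treatment_spec` list.
#' @export
treatment_spec <- function(label, legume_proportion, base_height, base_FM,
                           dm_content, n_conc_legume = 3.4, n_conc_grass = 1.5,
                           heterogeneity = 0.2,
                           texture_correlation_length_m = 0.3) {
  assert_that(legume_proportion >= 0 && legume_proportion <= 1,
              "legume proportion must be in [0, 1]")
  assert_that(base_height >= 0 && base_FM >= 0 && dm_content > 0 &&
                dm_content < 1, "invalid treatment parameters")
  structure(list(label = label, legume_proportion = legume_proportion,
                 base_height = base_height, base_FM = base_FM,
                 dm_content = dm_content, n_conc_legume = n_conc_legume,
                 n_conc_grass = n_conc_grass, heterogeneity = heterogeneity,
                 texture_correlation_length_m = texture_correlation_length_m),
            class = "treatment_spec")
}

#' Default treatment set
#'
#' Six treatments calibrated so that the default two-year experiment
#' produces annual fresh matter sums of roughly 13-90 t ha^-1 and annual N
#' fixation of roughly 70-350 kg ha^-1, inside the envelopes observed in
#' comparable legume-grass field trials.
#'
#' @return named list of six [treatment_spec()]s.
#' @export
default_treatments <- function() {
  list(
    CG   = treatment_spec("CG",   0.5, 0.50, 22, 0.15, n_conc_legume = 3.5,
                          heterogeneity = 0.30, texture_correlation_length_m = 0.25),
    LG   = treatment_spec("LG",   0.4, 0.45, 19, 0.16, n_conc_legume = 3.3,
                          heterogeneity = 0.30, texture_correlation_length_m = 0.30),
    L_CG = treatment_spec("L_CG", 1.0, 0.55, 25, 0.14, n_conc_legume = 3.3,
                          heterogeneity = 0.15, texture_correlation_length_m = 0.40),
    L_LG = treatment_spec("L_LG", 1.0, 0.50, 22, 0.15, n_conc_legume = 3.3,
                          heterogeneity = 0.15, texture_correlation_length_m = 0.45),
    G_CG = treatment_spec("G_CG", 0.0, 0.45, 10, 0.18,
                          heterogeneity = 0.15, texture_correlation_length_m = 0.15),
    G_LG = treatment_spec("G_LG", 0.0, 0.40,  7, 0.22,
                          heterogeneity = 0.15, texture_correlation_length_m = 0.20)
  )
}

#' Default year effects
#'
#' Two growing seasons: a drought year that suppresses legume growth
#' (multiplier 0.6) while mature grass grows tall with little biomass
#' (height multiplier 1.3), and a regular year in which the unfertilised
#' grass suffers nutrient deficiency (multiplier 0.7).
#'
#' @return list of per-year multiplier lists.
#' @export
default_years <- function() {
  list(
    list(year = 2018L, legume_mult = 0.6, grass_mult = 1.0, grass_height_mult = 1.3),
    list(year = 2019L, legume_mult = 1.0, grass_mult = 0.7, grass_height_mult = 1.0)
  )
}

#' Simulation configuration
#'
#' @param seed master seed for the whole scene.
#' @param n_replicates blocks (default 4).
#' @param treatments list of [treatment_spec()]s (default
#'   [default_treatments()]).
#' @param years list of year-effect lists (default [default_years()]).
#' @param harvests_per_year harvests per season (default 3).
#' @param plot_length_m,plot_width_m plot dimensions, m (default 12, 1.5).
#' @param excluded_strip_m destructively sampled strip at the plot
#'   entrance, removed from every zonal computation (default 1.5).
#' @param path_m bare-soil pathway width between plots and blocks (0.5).
#' @param point_density canopy scan density, points m^-2 (default 1000).
#' @param ground_density bare-ground scan density, points m^-2 (1500).
#' @param csh_cell_m canopy height raster cell, m (default 0.05).
#' @param ms_cell_m multispectral raster cell, m (default 0.045).
#' @param height_noise_sd per-point vertical measurement noise, m.
#' @param reflectance_sd amplitude of the spatial reflectance noise.
#' @param biomass_cv per-plot-harvest lognormal growth variability.
#' @param n_conc_sd additive noise on N concentration, % of DM.
#' @param exclusions data.frame (`plot_id`, `year`, `harvest`) of
#'   plot-harvests excluded from the analysis; `NULL` = the default four
#'   plots at the last harvest of the last year; `"none"` disables.
#' @param cell_budget maximum number of scene raster cells allowed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_replicates = 4L,
                       treatments = default_treatments(),
                       years = default_years(), harvests_per_year = 3L,
                       plot_length_m = 12, plot_width_m = 1.5,
                       excluded_strip_m = 1.5, path_m = 0.5,
                       point_density = 1000, ground_density = 1500,
                       csh_cell_m = 0.05, ms_cell_m = 0.045,
                       height_noise_sd = 0.003, reflectance_sd = 0.02,
                       biomass_cv = 0.08, n_conc_sd = 0.1,
                       exclusions = NULL, cell_budget = 5e6) {
  assert_that(n_replicates >= 1 && harvests_per_year >= 1,
              "replicates and harvests must be at least 1")
  assert_that(plot_length_m > 0 && plot_width_m > 0 && path_m >= 0,
              "plot dimensions must be positive")
  assert_that(csh_cell_m > 0 && ms_cell_m > 0 &&
                csh_cell_m < min(plot_length_m, plot_width_m) &&
                ms_cell_m < min(plot_length_m, plot_width_m),
              "cell sizes must be positive and smaller than the plot")
  assert_that(point_density > 0 && ground_density > 0,
              "point densities must be positive")
  nt <- length(treatments)
  scene_w <- nt * plot_width_m + (nt - 1) * path_m
  scene_l <- n_replicates * plot_length_m + (n_replicates - 1) * path_m
  n_cells <- ceiling(scene_w / ms_cell_m) * ceiling(scene_l / ms_cell_m)
  if (n_cells > cell_budget) {
    stop_fusion(sprintf("scene raster of %d cells exceeds the cell budget (%g)",
                        n_cells, cell_budget))
  }
  cfg <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
              treatments = treatments, years = years,
              harvests_per_year = as.integer(harvests_per_year),
              plot_length_m = plot_length_m, plot_width_m = plot_width_m,
              excluded_strip_m = excluded_strip_m, path_m = path_m,
              point_density = point_density, ground_density = ground_density,
              csh_cell_m = csh_cell_m, ms_cell_m = ms_cell_m,
              height_noise_sd = height_noise_sd, reflectance_sd = reflectance_sd,
              biomass_cv = biomass_cv, n_conc_sd = n_conc_sd,
              exclusions = exclusions,
              scene_width_m = scene_w, scene_length_m = scene_l)
  class(cfg) <- "sim_config"
  cfg
}

# Smooth terrain under the whole experiment (metres a.s.l.).
dem_elevation <- function(x, y) 227 + 0.004 * x + 0.002 * y

#' Gaussian random field on a grid (FFT-filtered white noise)
#'
#' White noise smoothed with a Gaussian kernel of the given correlation
#' length via circular convolution, then standardised to mean 0 / sd 1.
#'
#' @param nr,nc grid dimensions.
#' @param cell cell size, m.
#' @param corr_len correlation length, m; `<= 0` returns plain white noise.
#' @return `nr x nc` numeric matrix.
#' @export
gaussian_random_field <- function(nr, nc, cell, corr_len) {
  W <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len <= cell / 2) {
    return((W - mean(W)) / sd(W))
  }
  dy <- pmin(0:(nr - 1), nr - 0:(nr - 1)) * cell
  dx <- pmin(0:(nc - 1), nc - 0:(nc - 1)) * cell
  k <- exp(-outer(dy^2, dx^2, `+`) / (2 * corr_len^2))
  Fk <- fft(k)
  Fw <- fft(W)
  f <- Re(fft(Fw * Fk, inverse = TRUE)) / length(W)
  (f - mean(f)) / sd(f)
}

#' Simulate the laser scan of one plot
#'
#' Canopy returns follow a right-skewed height distribution (Beta(2, 5)
#' scaled so its mean equals `base_height * climate_mult`), modulated by a
#' multiplicative Gaussian random field whose amplitude and correlation
#' length come from the treatment (mixtures rougher than pure stands);
#' ground returns appear where the canopy leaves gaps (1 - cover).  All
#' returns sit on the terrain surface plus measurement noise.
#'
#' @param spec a [treatment_spec()].
#' @param footprint list/row with `xmin`, `xmax`, `ymin`, `ymax`.
#' @param climate_mult multiplier on `base_height` (default 1).
#' @param density point density, m^-2.
#' @param seed integer seed.
#' @param cover canopy cover fraction in `[0, 1]`.
#' @param height_noise_sd vertical noise sd, m.
#' @param cell grid step used for the heterogeneity field, m.
#' @return data.frame with `x`, `y`, `z`.
#' @export
simulate_plot_cloud <- function(spec, footprint, climate_mult = 1,
                                density = 1000, seed = 1, cover = 0.9,
                                height_noise_sd = 0.003, cell = 0.05) {
  assert_that(density > 0, "point density must be positive")
  with_seed(seed, {
    w <- footprint$xmax - footprint$xmin
    l <- footprint$ymax - footprint$ymin
    n <- rpois(1, density * w * l)
    n <- max(n, 1L)
    x <- runif(n, footprint$xmin, footprint$xmax)
    y <- runif(n, footprint$ymin, footprint$ymax)
    z <- dem_elevation(x, y) + rnorm(n, 0, height_noise_sd)
    mean_h <- spec$base_height * climate_mult
    if (mean_h > 0) {
      nrg <- max(2L, ceiling(l / cell)); ncg <- max(2L, ceiling(w / cell))
      fld <- gaussian_random_field(nrg, ncg, cell,
                                   spec$texture_correlation_length_m)
      fac <- pmax(1 + spec$heterogeneity * fld, 0.2)
      ic <- pmin(pmax(floor((y - footprint$ymin) / cell) + 1, 1), nrg)
      jc <- pmin(pmax(floor((x - footprint$xmin) / cell) + 1, 1), ncg)
      is_canopy <- runif(n) < cover
      h <- mean_h * fac[cbind(ic, jc)] * rbeta(n, 2, 5) * 3.5
      z <- z + ifelse(is_canopy, h, 0)
    }
    data.frame(x = x, y = y, z = z)
  })
}

# Per-plot reflectance targets as a saturating function of dry matter
# yield; NIR rises and red falls with biomass, the legume fraction
# shifts the green and red-edge levels slightly.
band_targets <- function(dm_t_ha, legume_prop) {
  v <- dm_t_ha / (dm_t_ha + 4)
  c(green    = 0.16 - 0.07 * v + 0.01 * legume_prop,
    red      = 0.28 - 0.22 * v,
    red_edge = 0.25 + 0.15 * v + 0.02 * legume_prop,
    nir      = 0.18 + 0.52 * v)
}

soil_reflectance <- c(green = 0.13, red = 0.20, red_edge = 0.23, nir = 0.26)

#' Simulate the four-band reflectance rasters of one harvest
#'
#' A scene-wide grid at the multispectral resolution: pathways carry
#' bare-soil reflectance, each plot carries its biomass-driven band levels
#' (NIR saturating upward, red downward with dry matter) plus a spatially
#' autocorrelated noise field with the treatment's correlation length, so
#' texture features carry treatment signal.  Values are clipped to [0, 1];
#' generation fails if more than 5% of plot cells need clipping.
#'
#' @param truth truth-table rows of one year-harvest (needs `plot_id`,
#'   `DM_t_ha`, `legume_prop`, `treatment`).
#' @param polygons plot rectangle table.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return named list of four [raster_grid()]s.
#' @export
simulate_band_rasters <- function(truth, polygons, config, seed = 1) {
  cell <- config$ms_cell_m
  nr <- ceiling(config$scene_length_m / cell)
  nc <- ceiling(config$scene_width_m / cell)
  with_seed(seed, {
    bands <- lapply(soil_reflectance, function(s) {
      matrix(s, nr, nc) + matrix(rnorm(nr * nc, 0, 0.3 * config$reflectance_sd), nr, nc)
    })
    xs <- (seq_len(nc) - 0.5) * cell
    ys <- (seq_len(nr) - 0.5) * cell
    for (k in seq_len(nrow(truth))) {
      tr <- truth[k, ]
      p <- polygons[polygons$plot_id == tr$plot_id, ]
      assert_that(nrow(p) == 1, "polygon missing for a truth record")
      assert_that(p$xmin >= 0 && p$ymin >= 0 &&
                    p$xmax <= nc * cell + 1e-9 && p$ymax <= nr * cell + 1e-9,
                  "plot polygon not covered by the raster extent")
      jc <- which(xs >= p$xmin & xs < p$xmax)
      ic <- which(ys >= p$ymin & ys < p$ymax)
      spec <- config$treatments[[tr$treatment]]
      tgt <- band_targets(tr$DM_t_ha, tr$legume_prop)
      n_clip <- 0L
      for (b in names(bands)) {
        fld <- gaussian_random_field(length(ic), length(jc), cell,
                                     spec$texture_correlation_length_m)
        v <- tgt[[b]] + config$reflectance_sd * fld +
          rnorm(length(ic) * length(jc), 0, 0.3 * config$reflectance_sd)
        n_clip <- n_clip + sum(v < 0 | v > 1)
        bands[[b]][ic, jc] <- pmin(pmax(v, 0), 1)
      }
      if (n_clip > 0.05 * 4 * length(ic) * length(jc)) {
        stop_fusion(sprintf("plot %s: reflectance clipping budget exceeded", tr$plot_id))
      }
    }
    lapply(bands, function(m) raster_grid(pmin(pmax(m, 0), 1),
                                          x0 = 0, y0 = 0, cell = cell))
  })
}

# Randomised complete block layout: treatments permuted within each block,
# blocks stacked along y, plots side by side along x, bare pathways between.
layout_plots <- function(config) {
  nt <- length(config$treatments)
  labels <- names(config$treatments)
  rows <- list()
  pid <- 0L
  for (b in seq_len(config$n_replicates)) {
    ord <- sample(labels)
    y0 <- (b - 1) * (config$plot_length_m + config$path_m)
    for (t in seq_len(nt)) {
      pid <- pid + 1L
      x0 <- (t - 1) * (config$plot_width_m + config$path_m)
      rows[[pid]] <- data.frame(
        plot_id = sprintf("P%02d", pid), treatment = ord[t], block = b,
        xmin = x0, xmax = x0 + config$plot_width_m,
        ymin = y0, ymax = y0 + config$plot_length_m)
    }
  }
  do.call(rbind, rows)
}

default_exclusions <- function(config, polygons) {
  last_year <- config$years[[length(config$years)]]$year
  picks <- list(c("CG", 1), c("LG", 2), c("G_CG", 3), c("G_LG", 4))
  rows <- lapply(picks, function(pk) {
    hit <- polygons[polygons$treatment == pk[1] & polygons$block == as.integer(pk[2]), ]
    if (nrow(hit) == 0) return(NULL)
    data.frame(plot_id = hit$plot_id[1], year = last_year,
               harvest = config$harvests_per_year)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Simulate a complete two-year field experiment
#'
#' Generates the full scene bundle the downstream pipeline consumes: a
#' randomised complete block layout of plot polygons, a ground-truth table
#' (fresh/dry matter, N concentration and amount, legume proportion) for
#' every retained plot-harvest, one laser-scan point cloud per
#' plot-harvest plus a bare-ground scan, and four reflectance rasters per
#' harvest.  Biomass and canopy height share a latent lognormal growth
#' factor so heights are genuinely predictive of yields.  Deterministic
#' for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @param generate_clouds,generate_rasters set `FALSE` to skip the heavy
#'   sensor layers when only design bookkeeping is needed.
#' @return list with `config`, `polygons`, `truth`, `excluded`, `clouds`
#'   (named `plotid_year_harvest`), `ground_cloud`, `bands` (named
#'   `year_harvest`, each a 4-band list).
#' @export
simulate_experiment <- function(config = sim_config(), generate_clouds = TRUE,
                                generate_rasters = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    polygons <- layout_plots(config)
    excl <- if (is.null(config$exclusions)) {
      default_exclusions(config, polygons)
    } else if (identical(config$exclusions, "none")) {
      NULL
    } else config$exclusions

    truth <- list(); clouds <- list(); bands <- list()
    k <- 0L
    for (yr in config$years) {
      for (h in seq_len(config$harvests_per_year)) {
        hrows <- list()
        for (i in seq_len(nrow(polygons))) {
          p <- polygons[i, ]
          if (!is.null(excl) &&
              any(excl$plot_id == p$plot_id & excl$year == yr$year &
                  excl$harvest == h)) next
          spec <- config$treatments[[p$treatment]]
          k <- k + 1L
          g <- exp(rnorm(1, 0, config$biomass_cv))
          bio_mult <- spec$legume_proportion * yr$legume_mult +
            (1 - spec$legume_proportion) * yr$grass_mult
          fm <- spec$base_FM * bio_mult * g
          dmc <- min(max(spec$dm_content * (1 + rnorm(1, 0, 0.05)), 0.05), 0.6)
          dm <- fm * dmc
          nconc <- spec$legume_proportion * spec$n_conc_legume +
            (1 - spec$legume_proportion) * spec$n_conc_grass +
            rnorm(1, 0, config$n_conc_sd)
          nconc <- max(nconc, 0.5)
          rec <- data.frame(
            plot_id = p$plot_id, year = yr$year, harvest = h,
            treatment = p$treatment, block = p$block,
            FM_t_ha = fm, DM_t_ha = dm, N_conc_pct = nconc,
            N_amount_kg_ha = n_amount(dm, nconc),
            legume_prop = spec$legume_proportion)
          hrows[[length(hrows) + 1L]] <- rec
          if (generate_clouds) {
            h_mult <- spec$legume_proportion * yr$legume_mult +
              (1 - spec$legume_proportion) * yr$grass_height_mult
            cover <- fm / (fm + 5)
            key <- sprintf("%s_%d_%d", p$plot_id, yr$year, h)
            clouds[[key]] <- simulate_plot_cloud(
              spec, p, climate_mult = h_mult * g^0.7,
              density = config$point_density,
              seed = derive_seed(config$seed, k), cover = cover,
              height_noise_sd = config$height_noise_sd,
              cell = config$csh_cell_m)
          }
        }
        htruth <- do.call(rbind, hrows)
        truth[[length(truth) + 1L]] <- htruth
        if (generate_rasters) {
          bands[[sprintf("%d_%d", yr$year, h)]] <- simulate_band_rasters(
            htruth, polygons, config,
            seed = derive_seed(config$seed, 100000 + length(truth)))
        }
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    ground <- NULL
    if (generate_clouds) {
      ng <- rpois(1, config$ground_density * config$scene_width_m *
                    config$scene_length_m)
      gx <- runif(ng, 0, config$scene_width_m)
      gy <- runif(ng, 0, config$scene_length_m)
      ground <- data.frame(x = gx, y = gy,
                           z = dem_elevation(gx, gy) +
                             rnorm(ng, 0, config$height_noise_sd))
    }
    list(config = config, polygons = polygons, truth = truth,
         excluded = excl, clouds = if (generate_clouds) clouds else NULL,
         ground_cloud = ground, bands = if (generate_rasters) bands else NULL)
  })
}

#' Export a simulated scene to plain-text files
#'
#' Writes the truth table and exclusion list as CSV, plot polygons as
#' GeoJSON, point clouds as whitespace XYZ, and band rasters as ESRI
#' ASCII grids under `dir`.
#'
#' @param scene result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- scene$truth
  out <- data.frame(plot_id = tr$plot_id, year = tr$year, harvest = tr$harvest,
                    treatment = tr$treatment, FM_t_ha = tr$FM_t_ha,
                    DM_t_ha = tr$DM_t_ha, N_conc_pct = tr$N_conc_pct,
                    N_amount_kg_ha = tr$N_amount_kg_ha,
                    legume_prop = tr$legume_prop)
  write.csv(out, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(scene$excluded)) {
    write.csv(scene$excluded, file.path(dir, "excluded.csv"), row.names = FALSE)
  }
  write_plots_geojson(scene$polygons, file.path(dir, "plots.geojson"))
  if (!is.null(scene$clouds)) {
    cd <- file.path(dir, "clouds")
    dir.create(cd, showWarnings = FALSE)
    for (nm in names(scene$clouds)) {
      write_xyz(scene$clouds[[nm]], file.path(cd, paste0(nm, ".xyz")))
    }
    write_xyz(scene$ground_cloud, file.path(cd, "ground.xyz"))
  }
  if (!is.null(scene$bands)) {
    bd <- file.path(dir, "bands")
    dir.create(bd, showWarnings = FALSE)
    for (nm in names(scene$bands)) {
      for (b in names(scene$bands[[nm]])) {
        write_ascii_grid(scene$bands[[nm]][[b]],
                         file.path(bd, sprintf("%s_%s.asc", nm, b)))
      }
    }
  }
  invisible(dir)
}
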