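# Content hash of an R object (serialised to a temp file, md5).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

# Tiny content-addressed cache: evaluates `expr` once per (name, key)
# and replays the stored result afterwards.
cache_stage <- function(cache_dir, name, key, expr) {
  if (is.null(cache_dir)) return(force(expr))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cache_dir, sprintf("%s_%s.rds", name, key))
  if (file.exists(path)) return(readRDS(path))
  out <- force(expr)
  saveRDS(out, path)
  out
}

#' Extract the per-plot feature tables from a simulated scene
#'
#' Runs the height, spectral and texture stages over every plot-harvest:
#' digital surface model (cell maximum) and bare-ground elevation model
#' (cell mean of the ground scan) at 5 cm, their difference as crop
#' surface height, the 15 height metrics; zonal band means and the 13
#' vegetation indices at the multispectral resolution; and the eight
#' sliding-window Haralick texture means of the mean-height raster and of
#' each band.  The canopy height rasters are quantized over `[0, p99.9]`
#' of the whole scene so texture is comparable across plots; band crops
#' are quantized over their own range.
#'
#' @param scene result of [simulate_experiment()] (clouds and bands
#'   present).
#' @param radius,n_levels texture window radius and gray levels.
#' @param aggregator DSM aggregator (default `"max"`).
#' @return list of five data.frames (`csh_metrics`, `csh_texture`,
#'   `band_means`, `vis`, `band_texture`), each keyed by
#'   `plot_id`, `year`, `harvest`.
#' @export
extract_features <- function(scene, radius = 2, n_levels = 8,
                             aggregator = "max") {
  cfg <- scene$config
  assert_that(!is.null(scene$clouds) && !is.null(scene$bands),
              "scene must include point clouds and band rasters")
  cell <- cfg$csh_cell_m
  strip <- cfg$excluded_strip_m
  polys <- scene$polygons

  # year-invariant DEM per plot from the bare-ground scan
  dems <- list()
  for (i in seq_len(nrow(polys))) {
    p <- polys[i, ]
    g <- scene$ground_cloud
    sel <- g$x >= p$xmin & g$x < p$xmax & g$y >= p$ymin & g$y < p$ymax
    dems[[p$plot_id]] <- rasterize_surface(
      g[sel, ], x0 = p$xmin, y0 = p$ymin, cell = cell,
      nrow = round((p$ymax - p$ymin) / cell),
      ncol = round((p$xmax - p$xmin) / cell), aggregator = "mean")
  }

  keys <- scene$truth[, c("plot_id", "year", "harvest")]
  n <- nrow(keys)
  csh_max <- vector("list", n); csh_mean <- vector("list", n)
  for (k in seq_len(n)) {
    key <- sprintf("%s_%d_%d", keys$plot_id[k], keys$year[k], keys$harvest[k])
    cloud <- scene$clouds[[key]]
    assert_that(!is.null(cloud), sprintf("missing point cloud for %s", key))
    p <- polys[polys$plot_id == keys$plot_id[k], ]
    dem <- dems[[p$plot_id]]
    grid_args <- list(x0 = p$xmin, y0 = p$ymin, cell = cell,
                      nrow = nrow(dem$values), ncol = ncol(dem$values))
    dsm <- do.call(rasterize_surface, c(list(cloud), grid_args,
                                        list(aggregator = aggregator)))
    dsm_m <- do.call(rasterize_surface, c(list(cloud), grid_args,
                                          list(aggregator = "mean")))
    csh_max[[k]] <- compute_csh(dsm, dem)
    csh_mean[[k]] <- compute_csh(dsm_m, dem)
  }
  all_csh <- unlist(lapply(csh_mean, function(r) r$values[!is.na(r$values)]))
  csh_range <- c(0, max(quantile(all_csh, 0.999), 1e-6))

  met_rows <- list(); ctex_rows <- list(); bm_rows <- list()
  vi_rows <- list(); btex_rows <- list()
  band_cols <- c(green = "green", red = "red", rededge = "red_edge", nir = "nir")
  for (k in seq_len(n)) {
    p <- polys[polys$plot_id == keys$plot_id[k], ]
    keydf <- keys[k, , drop = FALSE]

    met <- plot_csh_metrics(csh_max[[k]], p, excluded_strip_m = strip)
    names(met) <- paste0("csh_", names(met))
    met_rows[[k]] <- cbind(keydf, as.data.frame(as.list(met)))

    tex <- texture_image(csh_mean[[k]], radius = radius, n_levels = n_levels,
                         value_range = csh_range)
    tm <- plot_texture_means(tex, p, excluded_strip_m = strip)
    names(tm) <- paste0("cshtex_", names(tm))
    ctex_rows[[k]] <- cbind(keydf, as.data.frame(as.list(tm)))

    bands <- scene$bands[[sprintf("%d_%d", keys$year[k], keys$harvest[k])]]
    assert_that(!is.null(bands), "missing band rasters for a harvest")
    bm <- zonal_band_means(bands, p, excluded_strip_m = strip)
    bmv <- bm; names(bmv) <- paste0("band_", names(band_cols))
    bm_rows[[k]] <- cbind(keydf, as.data.frame(as.list(bmv)))
    vi_rows[[k]] <- cbind(keydf, as.data.frame(as.list(compute_vis(bm))))

    btex <- numeric(0)
    for (b in names(band_cols)) {
      crop <- rg_crop(bands[[band_cols[[b]]]], p$xmin, p$xmax, p$ymin, p$ymax)
      texb <- texture_image(crop, radius = radius, n_levels = n_levels)
      tmb <- plot_texture_means(texb, p, excluded_strip_m = strip)
      names(tmb) <- paste0(b, "_", names(tmb))
      btex <- c(btex, tmb)
    }
    btex_rows[[k]] <- cbind(keydf, as.data.frame(as.list(btex)))
  }
  list(csh_metrics = do.call(rbind, met_rows),
       csh_texture = do.call(rbind, ctex_rows),
       band_means = do.call(rbind, bm_rows),
       vis = do.call(rbind, vi_rows),
       band_texture = do.call(rbind, btex_rows))
}

merge_keyed <- function(a, b, label) {
  keys <- c("plot_id", "year", "harvest")
  m <- merge(a, b, by = keys, all = FALSE)
  orphans <- setdiff(do.call(paste, a[keys]), do.call(paste, m[keys]))
  orphans <- c(orphans, setdiff(do.call(paste, b[keys]), do.call(paste, m[keys])))
  if (length(orphans) > 0) {
    stop_fusion(sprintf("key mismatch while joining %s: orphan rows %s",
                        label, paste(unique(orphans), collapse = "; ")))
  }
  m
}

#' Assemble the modeling feature tables
#'
#' Joins the five feature sources and the ground truth on
#' (`plot_id`, `year`, `harvest`) and builds the three predictor
#' variants: `CSH` = 15 height metrics + 8 height-texture features (23),
#' `MS` = 4 band means + 13 vegetation indices + 32 band-texture
#' features (49), `Fusion` = their union (72).  Key mismatches raise an
#' error listing the orphan keys; rows with any missing predictor are
#' dropped with a message.  The N-fixation response is attached from the
#' difference method and is absent (`NA`) for pure-grass rows.
#'
#' @param csh_metrics,csh_texture,band_means,vis,band_texture keyed
#'   feature data.frames (from [extract_features()]).
#' @param truth ground-truth table with `block` and `N_amount_kg_ha`.
#' @return list with `tables` (one data.frame per variant) and
#'   `predictors` (character vectors per variant).
#' @export
assemble_features <- function(csh_metrics, csh_texture, band_means, vis,
                              band_texture, truth) {
  keys <- c("plot_id", "year", "harvest")
  feat <- merge_keyed(csh_metrics, csh_texture, "height features")
  feat <- merge_keyed(feat, band_means, "band means")
  feat <- merge_keyed(feat, vis, "vegetation indices")
  feat <- merge_keyed(feat, band_texture, "band texture")
  pred_cols <- setdiff(names(feat), keys)
  drop <- !stats::complete.cases(feat[, pred_cols, drop = FALSE])
  if (any(drop)) {
    message(sprintf("%d rows dropped: missing predictor values", sum(drop)))
    feat <- feat[!drop, , drop = FALSE]
  }
  meta <- truth[, c(keys, "treatment", "block", "FM_t_ha", "DM_t_ha")]
  meta$mixture <- mixture_of(meta$treatment)
  nf <- nfix_table(truth)
  meta <- merge(meta, nf[, c(keys, "NFix_kg_ha")], by = keys, all.x = TRUE)
  tab <- merge_keyed(meta, feat, "truth")
  tab <- tab[order(tab$year, tab$harvest, tab$plot_id), ]
  rownames(tab) <- NULL
  csh_cols <- grep("^csh_|^cshtex_", pred_cols, value = TRUE)
  ms_cols <- setdiff(pred_cols, csh_cols)
  list(tables = list(CSH = tab, MS = tab, Fusion = tab),
       predictors = list(CSH = csh_cols, MS = ms_cols,
                         Fusion = c(csh_cols, ms_cols)))
}

response_column <- function(response) {
  switch(response, FM = "FM_t_ha", DM = "DM_t_ha", NFix = "NFix_kg_ha",
         stop_fusion(sprintf("unknown response '%s'", response)))
}

#' Run the full sensor-fusion analysis
#'
#' Simulate (or reuse) a scene, extract all features, assemble the three
#' predictor variants, run the three-step variable selection per
#' response and variant, and validate with repeated stratified splits.
#' Fully deterministic for a fixed config seed; with `cache_dir` set,
#' the scene and feature stages are content-addressed by a hash of the
#' configuration and replayed instead of recomputed.
#'
#' @param config a [sim_config()].
#' @param responses subset of `c("FM", "DM", "NFix")`.
#' @param variants subset of `c("CSH", "MS", "Fusion")`.
#' @param n_splits validation splits per model (default 100).
#' @param do_selection run variable selection first (default `TRUE`).
#' @param selection_runs forest counts `c(threshold, interpretation,
#'   prediction)` for the selection steps.
#' @param out_dir optional directory for the summary JSON and per-split
#'   CSVs.
#' @param cache_dir optional stage cache directory.
#' @return list with `scene_summary`, `selection`, `models`, `summary`
#'   (per response x variant medians and quartiles).
#' @export
run_pipeline <- function(config = sim_config(), responses = c("FM", "DM", "NFix"),
                         variants = c("CSH", "MS", "Fusion"), n_splits = 100,
                         do_selection = TRUE, selection_runs = c(50, 25, 25),
                         out_dir = NULL, cache_dir = NULL) {
  assert_that(length(responses) >= 1 && length(variants) >= 1,
              "need at least one response and one variant")
  cfg_hash <- object_hash(config)
  scene <- cache_stage(cache_dir, "scene", cfg_hash,
                       simulate_experiment(config))
  feats <- cache_stage(cache_dir, "features", cfg_hash,
                       extract_features(scene))
  asm <- assemble_features(feats$csh_metrics, feats$csh_texture,
                           feats$band_means, feats$vis, feats$band_texture,
                           scene$truth)
  selection <- list(); models <- list(); summary_rows <- list()
  for (resp in responses) {
    rc <- response_column(resp)
    for (v in variants) {
      tab <- asm$tables[[v]]
      tab <- tab[!is.na(tab[[rc]]), , drop = FALSE]
      preds <- asm$predictors[[v]]
      key <- paste(resp, v, sep = "_")
      sel_seed <- derive_seed(config$seed, 31 * match(resp, responses) +
                                match(v, variants))
      use_preds <- preds
      if (do_selection) {
        sel <- select_variables(tab[, preds, drop = FALSE], tab[[rc]],
                                n_runs_threshold = selection_runs[1],
                                n_runs_interp = selection_runs[2],
                                n_runs_pred = selection_runs[3],
                                seed = sel_seed)
        selection[[key]] <- sel
        use_preds <- sel$prediction_set
      }
      mod <- repeated_modeling(tab, use_preds, rc, n_splits = n_splits,
                               seed = derive_seed(config$seed, 1000 +
                                 match(resp, responses) * 10 + match(v, variants)))
      models[[key]] <- mod
      summary_rows[[key]] <- data.frame(
        response = resp, variant = v, n = nrow(tab),
        n_predictors = length(use_preds),
        r2_median = mod$metrics$r2_val[["median"]],
        r2_q25 = mod$metrics$r2_val[["q25"]],
        r2_q75 = mod$metrics$r2_val[["q75"]],
        rrmsep_median = mod$metrics$rrmsep[["median"]],
        rrmsep_q25 = mod$metrics$rrmsep[["q25"]],
        rrmsep_q75 = mod$metrics$rrmsep[["q75"]])
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  out <- list(scene_summary = list(n_plots = nrow(scene$polygons),
                                   n_truth_rows = nrow(scene$truth),
                                   seed = config$seed, config_hash = cfg_hash),
              selection = selection, models = models, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(schema_version = "1.0", scene = out$scene_summary,
           summary = summary,
           selection = lapply(selection, function(s) {
             list(threshold = s$threshold_value,
                  retained = s$retained_after_threshold,
                  interpretation = s$interpretation_set,
                  prediction = s$prediction_set)
           })),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    for (key in names(models)) {
      write.csv(models[[key]]$splits,
                file.path(out_dir, sprintf("splits_%s.csv", key)),
                row.names = FALSE)
    }
  }
  out
}
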