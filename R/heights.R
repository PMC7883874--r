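#' Rasterize a point cloud onto a regular grid
#'
#' Overlays a square-cell grid on the cloud and aggregates the z-values of
#' the points falling in each cell (half-open cell intervals).  Cells that
#' receive no point are nodata (`NA`).  The default aggregator `max` gives
#' a top-of-canopy digital surface model; `mean` and `p95` are available
#' for sensitivity analyses and for bare-ground elevation models.
#'
#' @param cloud data.frame with numeric `x`, `y`, `z` (metres).
#' @param x0,y0 grid origin; defaults snap to the cloud bounding box.
#' @param cell cell size in metres (default 0.05).
#' @param nrow,ncol grid dimensions; default covers the cloud.
#' @param aggregator one of `"max"`, `"mean"`, `"p95"`.
#' @return a [raster_grid()].
#' @export
rasterize_surface <- function(cloud, x0 = NULL, y0 = NULL, cell = 0.05,
                              nrow = NULL, ncol = NULL,
                              aggregator = c("max", "mean", "p95")) {
  aggregator <- match.arg(aggregator)
  assert_that(is.data.frame(cloud) && nrow(cloud) >= 1,
              "point cloud must contain at least one point")
  assert_that(all(is.finite(cloud$x)) && all(is.finite(cloud$y)) &&
              all(is.finite(cloud$z)), "point coordinates must be finite")
  x0 <- x0 %||% (floor(min(cloud$x) / cell) * cell)
  y0 <- y0 %||% (floor(min(cloud$y) / cell) * cell)
  ncol <- ncol %||% max(1L, ceiling((max(cloud$x) - x0) / cell + 1e-9))
  nrow <- nrow %||% max(1L, ceiling((max(cloud$y) - y0) / cell + 1e-9))
  jc <- floor((cloud$x - x0) / cell) + 1L
  ic <- floor((cloud$y - y0) / cell) + 1L
  keep <- jc >= 1L & jc <= ncol & ic >= 1L & ic <= nrow
  assert_that(any(keep), "grid does not cover any point of the cloud")
  idx <- (jc[keep] - 1L) * nrow + ic[keep]
  z <- cloud$z[keep]
  agg <- switch(aggregator,
    max  = function(v) max(v),
    mean = function(v) mean(v),
    p95  = function(v) unname(quantile(v, 0.95, type = 7)))
  cellv <- vapply(split(z, idx), agg, numeric(1))
  m <- matrix(NA_real_, nrow = nrow, ncol = ncol)
  m[as.integer(names(cellv))] <- cellv
  raster_grid(m, x0 = x0, y0 = y0, cell = cell)
}

#' Crop surface height raster (DSM minus DEM)
#'
#' Cellwise difference of a digital surface model and a digital elevation
#' model on identical grids.  Nodata in either input propagates; negative
#' heights (ground-measurement noise) are clamped to zero and counted in
#' the `"n_clamped"` attribute.
#'
#' @param dsm,dem [raster_grid()]s with identical geometry.
#' @return a [raster_grid()] of canopy heights (m) with attribute
#'   `n_clamped`.
#' @export
compute_csh <- function(dsm, dem) {
  if (!rg_same_geometry(dsm, dem)) {
    stop_fusion(sprintf("DSM and DEM grids differ: [%s] vs [%s]",
                        rg_geometry_string(dsm), rg_geometry_string(dem)))
  }
  v <- dsm$values - dem$values
  n_clamped <- sum(v < 0, na.rm = TRUE)
  v[v < 0] <- 0
  out <- raster_grid(v, x0 = dsm$x0, y0 = dsm$y0, cell = dsm$cell, crs = dsm$crs)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Canopy height relief
#'
#' Vertical-distribution descriptor `(mean - min) / (max - min)`, in
#' `[0, 1]`; defined as 0 for a flat canopy (`max == min`).
#'
#' @param values numeric vector of at least two height values.
#' @return unitless scalar.
#' @export
canopy_height_relief <- function(values) {
  assert_that(length(values) >= 2, "canopy height relief needs >= 2 values")
  rng <- max(values) - min(values)
  if (rng == 0) return(0)
  (mean(values) - min(values)) / rng
}

csh_metric_names <- function() {
  c("mean", "min", "max", "median", "variance", "sd", "range", "mode",
    "skewness", "kurtosis", "relief", "p25", "p75", "p90", "p95")
}

# Fisher-Pearson moment coefficient of skewness (g1) and excess kurtosis (g2).
moment_skewness <- function(v) {
  m <- mean(v); n <- length(v)
  m2 <- sum((v - m)^2) / n
  if (m2 == 0) return(0)
  (sum((v - m)^3) / n) / m2^1.5
}

moment_kurtosis <- function(v) {
  m <- mean(v); n <- length(v)
  m2 <- sum((v - m)^2) / n
  if (m2 == 0) return(0)
  (sum((v - m)^4) / n) / m2^2 - 3
}

# Mode of a continuous sample: midpoint of the most populated 1 cm
# histogram bin over [0, max]; ties resolved toward the lower bin.
height_mode <- function(v, bin = 0.01) {
  if (max(v) == min(v)) return(v[1])
  lo <- min(0, min(v))
  breaks <- seq(lo, max(v) + bin, by = bin)
  h <- hist(v, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Per-plot crop surface height metrics
#'
#' Computes the 15 distributional metrics of the canopy height values
#' pooled over all valid raster cells whose centres fall inside the plot
#' polygon, after discarding the destructively sampled strip at the plot
#' entrance: mean, min, max, median, variance, sd, range, mode, skewness
#' (Fisher-Pearson g1), excess kurtosis (g2), canopy height relief and the
#' 25/75/90/95 percentiles (type-7 linear interpolation).
#'
#' @param csh a [raster_grid()] of canopy heights.
#' @param polygon two-column vertex matrix, or a plot row with
#'   `xmin`/`xmax`/`ymin`/`ymax`.
#' @param excluded_strip_m strip width removed from the low-y end of the
#'   plot (default 1.5 m).
#' @return named numeric vector of the 15 metrics (metres except variance
#'   in m^2 and the unitless shape descriptors).
#' @export
plot_csh_metrics <- function(csh, polygon, excluded_strip_m = 1.5) {
  if (is.data.frame(polygon)) polygon <- plot_polygon(polygon)
  v <- rg_extract_polygon(csh, polygon, strip_m = excluded_strip_m)
  assert_that(length(v) >= 2,
              "fewer than 2 valid canopy height cells inside the plot")
  degenerate <- max(v) == min(v)
  if (degenerate) {
    warning("flat canopy: relief, skewness and kurtosis set to 0")
  }
  q <- quantile(v, c(0.25, 0.5, 0.75, 0.90, 0.95), type = 7, names = FALSE)
  c(mean = mean(v), min = min(v), max = max(v), median = q[2],
    variance = var(v), sd = sd(v), range = max(v) - min(v),
    mode = height_mode(v),
    skewness = if (degenerate) 0 else moment_skewness(v),
    kurtosis = if (degenerate) 0 else moment_kurtosis(v),
    relief = canopy_height_relief(v),
    p25 = q[1], p75 = q[3], p90 = q[4], p95 = q[5])
}
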