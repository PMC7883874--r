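#' Zonal mean reflectance per band
#'
#' Mean over the non-nodata cells of each band raster whose centres fall
#' inside the plot polygon, after removing the destructively sampled strip.
#'
#' @param bands named list of four [raster_grid()]s
#'   (`green`, `red`, `red_edge`, `nir`), co-registered.
#' @param polygon vertex matrix or plot rectangle row.
#' @param excluded_strip_m strip removed from the low-y plot end (m).
#' @return named numeric vector of four band means in `[0, 1]`.
#' @export
zonal_band_means <- function(bands, polygon, excluded_strip_m = 1.5) {
  stopifnot(all(c("green", "red", "red_edge", "nir") %in% names(bands)))
  if (is.data.frame(polygon)) polygon <- plot_polygon(polygon)
  out <- vapply(c("green", "red", "red_edge", "nir"), function(b) {
    v <- rg_extract_polygon(bands[[b]], polygon, strip_m = excluded_strip_m)
    assert_that(length(v) > 0,
                sprintf("no valid %s cells inside the plot polygon", b))
    mean(v)
  }, numeric(1))
  names(out) <- c("green", "red", "red_edge", "nir")
  out
}

#' Vegetation index registry
#'
#' Declarative list mapping index names to formulas over the four band
#' means `G`, `R`, `RE`, `N`.  The default set of 13 indices spans the
#' normalised-difference family (NDVI, GNDVI, NDRE), simple and
#' chlorophyll ratios (RVI, GRVI, CIgreen, CIrededge), soil-adjusted
#' indices (SAVI, OSAVI, MSAVI2, EVI2) and renormalised/chlorophyll
#' absorption forms (RDVI, MCARI).  Replace or extend the registry to use
#' a different index set without touching the pipeline.
#'
#' @return named list of functions `(G, R, RE, N) -> value`.
#' @export
vi_registry <- function() {
  list(
    NDVI      = function(G, R, RE, N) (N - R) / (N + R),
    GNDVI     = function(G, R, RE, N) (N - G) / (N + G),
    NDRE      = function(G, R, RE, N) (N - RE) / (N + RE),
    RVI       = function(G, R, RE, N) N / R,
    GRVI      = function(G, R, RE, N) (G - R) / (G + R),
    CIgreen   = function(G, R, RE, N) N / G - 1,
    CIrededge = function(G, R, RE, N) N / RE - 1,
    SAVI      = function(G, R, RE, N) 1.5 * (N - R) / (N + R + 0.5),
    OSAVI     = function(G, R, RE, N) (N - R) / (N + R + 0.16),
    MSAVI2    = function(G, R, RE, N) (2 * N + 1 - sqrt((2 * N + 1)^2 - 8 * (N - R))) / 2,
    EVI2      = function(G, R, RE, N) 2.5 * (N - R) / (N + 2.4 * R + 1),
    RDVI      = function(G, R, RE, N) (N - R) / sqrt(N + R),
    MCARI     = function(G, R, RE, N) ((RE - R) - 0.2 * (RE - G)) * (RE / R)
  )
}

#' Compute vegetation indices from plot-mean reflectance
#'
#' Indices are evaluated on the plot-mean band reflectances (not per pixel
#' and then averaged).  A zero denominator yields `NA` for that index with
#' a warning rather than an error.
#'
#' @param band_means named numeric vector with `green`, `red`, `red_edge`,
#'   `nir`.
#' @param registry index registry, default [vi_registry()].
#' @return named numeric vector of index values.
#' @export
compute_vis <- function(band_means, registry = vi_registry()) {
  stopifnot(all(c("green", "red", "red_edge", "nir") %in% names(band_means)))
  G <- band_means[["green"]]; R <- band_means[["red"]]
  RE <- band_means[["red_edge"]]; N <- band_means[["nir"]]
  out <- vapply(names(registry), function(nm) {
    v <- suppressWarnings(registry[[nm]](G, R, RE, N))
    if (!is.finite(v)) {
      warning(sprintf("index %s undefined for these band means (set to NA)", nm))
      return(NA_real_)
    }
    v
  }, numeric(1))
  names(out) <- names(registry)
  out
}
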