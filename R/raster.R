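#' Georeferenced single-band raster grid
#'
#' Minimal in-memory container for a single-band raster: a numeric matrix
#' plus an origin, a square cell size and a nodata convention.  Row `i`
#' covers the y interval `[y0 + (i-1)*cell, y0 + i*cell)` and column `j`
#' the x interval `[x0 + (j-1)*cell, x0 + j*cell)` (half-open cells, row 1
#' at the southern edge).  Missing cells are stored as `NA`.
#'
#' @param values numeric matrix (rows = northing, cols = easting).
#' @param x0,y0 coordinates of the lower-left corner of cell (1,1), metres.
#' @param cell cell size in metres (> 0).
#' @param crs free-form CRS identifier, carried through unchanged.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, x0 = 0, y0 = 0, cell = 0.05, crs = NA_character_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(is.numeric(cell) && length(cell) == 1 && cell > 0,
              "cell size must be a single positive number")
  structure(
    list(values = values, x0 = as.numeric(x0), y0 = as.numeric(y0),
         cell = as.numeric(cell), crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, %.4g m cell, origin (%.3f, %.3f), %d NA\n",
              nrow(x$values), ncol(x$values), x$cell, x$x0, x$y0,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

rg_same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$cell - b$cell) < tol
}

rg_geometry_string <- function(r) {
  sprintf("%dx%d @ %.6g m, origin (%.6g, %.6g)",
          nrow(r$values), ncol(r$values), r$cell, r$x0, r$y0)
}

#' Cell-centre coordinates of a raster grid
#'
#' @param r a [raster_grid()].
#' @return list with matrices/vectors `x` (per column) and `y` (per row).
#' @export
rg_cell_centers <- function(r) {
  list(x = r$x0 + (seq_len(ncol(r$values)) - 0.5) * r$cell,
       y = r$y0 + (seq_len(nrow(r$values)) - 0.5) * r$cell)
}

#' Crop a raster grid to a bounding box (snapped to the cell lattice)
#'
#' @param r a [raster_grid()].
#' @param xmin,xmax,ymin,ymax bounding box in map units.
#' @return a [raster_grid()] covering the requested box.
#' @export
rg_crop <- function(r, xmin, xmax, ymin, ymax) {
  jc <- which(r$x0 + (seq_len(ncol(r$values)) - 0.5) * r$cell >= xmin &
              r$x0 + (seq_len(ncol(r$values)) - 0.5) * r$cell <= xmax)
  ic <- which(r$y0 + (seq_len(nrow(r$values)) - 0.5) * r$cell >= ymin &
              r$y0 + (seq_len(nrow(r$values)) - 0.5) * r$cell <= ymax)
  assert_that(length(ic) > 0 && length(jc) > 0, "crop box does not intersect raster")
  raster_grid(r$values[ic, jc, drop = FALSE],
              x0 = r$x0 + (min(jc) - 1) * r$cell,
              y0 = r$y0 + (min(ic) - 1) * r$cell,
              cell = r$cell, crs = r$crs)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over query points.  Points exactly on an edge are resolved by
#' the half-open crossing rule; for the axis-aligned rectangles used for
#' field plots this matches half-open cell membership.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly two-column matrix (x, y) of polygon vertices, open or closed.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  if (all(poly[1, ] == poly[nv, ])) { poly <- poly[-nv, , drop = FALSE]; nv <- nv - 1 }
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Extract the non-NA cell values of `r` whose centres fall inside `poly`
# after removing the sampling strip: cells whose centre lies within
# `strip_m` of the polygon's lowest y (the destructively sampled plot end)
# are discarded.  Returns a numeric vector (possibly empty).
rg_extract_polygon <- function(r, poly, strip_m = 0) {
  cc <- rg_cell_centers(r)
  xg <- rep(cc$x, each = length(cc$y))
  yg <- rep(cc$y, times = length(cc$x))
  keep <- point_in_polygon(xg, yg, poly)
  if (strip_m > 0) keep <- keep & (yg >= min(poly[, 2]) + strip_m)
  v <- as.vector(r$values)[keep]
  v[!is.na(v)]
}

#' Write / read a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text interchange format: a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by rows
#' from north to south.
#'
#' @param r a [raster_grid()].
#' @param path file path.
#' @param nodata numeric nodata marker written for `NA` cells.
#' @return `path`, invisibly (writer); a [raster_grid()] (reader).
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", r$x0),
               sprintf("yllcorner %.10g", r$y0),
               sprintf("cellsize %.10g", r$cell),
               sprintf("NODATA_value %.10g", nodata)), con)
  # ASCII grids are stored top row first
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(formatC(v[i, ], format = "g", digits = 9), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get_num <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- get_num("ncols"); nr <- get_num("nrows")
  x0 <- get_num("xllcorner"); y0 <- get_num("yllcorner")
  cell <- get_num("cellsize"); nodata <- get_num("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA_real_
  raster_grid(m, x0 = x0, y0 = y0, cell = cell)
}

#' Write / read a point cloud as whitespace-delimited XYZ text
#'
#' @param cloud data.frame with numeric columns `x`, `y`, `z`.
#' @param path file path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  write.table(cloud[, c("x", "y", "z")], path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  m <- read.table(path, col.names = c("x", "y", "z"))
  m
}

#' Write plot polygons as GeoJSON
#'
#' @param polygons data.frame with columns `plot_id`, `treatment`, `block`,
#'   `xmin`, `xmax`, `ymin`, `ymax` (axis-aligned plot rectangles).
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_plots_geojson <- function(polygons, path) {
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    p <- polygons[i, ]
    ring <- list(c(p$xmin, p$ymin), c(p$xmax, p$ymin), c(p$xmax, p$ymax),
                 c(p$xmin, p$ymax), c(p$xmin, p$ymin))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, treatment = p$treatment,
                           block = p$block),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plots_geojson
#' @export
read_plots_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(v) as.numeric(v[[1]]), 0)
    ys <- vapply(ring, function(v) as.numeric(v[[2]]), 0)
    data.frame(plot_id = f$properties$plot_id,
               treatment = f$properties$treatment,
               block = as.integer(f$properties$block),
               xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
  })
  do.call(rbind, rows)
}

# Rectangle helper: polygon matrix from a plot row.
plot_polygon <- function(p) {
  cbind(x = c(p$xmin, p$xmax, p$xmax, p$xmin),
        y = c(p$ymin, p$ymin, p$ymax, p$ymax))
}
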