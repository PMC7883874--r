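#' Quantize a raster to integer gray levels
#'
#' Linear binning of `value_range` into `n_levels` levels `0 .. G-1`:
#' `level = floor((v - lo) / (hi - lo) * G)` with the top edge clipped to
#' `G - 1` and out-of-range values clipped into the range.  Nodata cells
#' are preserved.
#'
#' @param r a [raster_grid()] (or a bare numeric matrix).
#' @param n_levels number of gray levels G (>= 2), default 8.
#' @param value_range length-2 numeric `c(lo, hi)`; default is the range
#'   of the valid cells.
#' @return object of the same kind as `r` holding integer levels.
#' @export
quantize <- function(r, n_levels = 8, value_range = NULL) {
  assert_that(n_levels >= 2, "n_levels must be at least 2")
  is_rg <- inherits(r, "raster_grid")
  v <- if (is_rg) r$values else as.matrix(r)
  valid <- !is.na(v)
  if (is.null(value_range)) {
    value_range <- range(v[valid])
    if (diff(value_range) == 0) {
      warning("constant raster: all cells quantized to level 0")
      value_range <- value_range + c(0, 1)
    }
  }
  assert_that(value_range[1] < value_range[2], "value_range must have min < max")
  q <- floor((pmin(pmax(v, value_range[1]), value_range[2]) - value_range[1]) /
             diff(value_range) * n_levels)
  q[q >= n_levels] <- n_levels - 1
  q[!valid] <- NA_real_
  if (is_rg) raster_grid(q, x0 = r$x0, y0 = r$y0, cell = r$cell, crs = r$crs) else q
}

#' Gray-level co-occurrence matrix of a window
#'
#' Counts all pixel pairs inside the window separated by each offset
#' `(dy, dx)` (dy = row step, dx = column step); with `symmetric = TRUE`
#' the transposed pairs are added, as in the usual rotationally paired
#' counting.  Pairs involving nodata pixels are skipped.  Counts are
#' normalised to probabilities.
#'
#' @param window integer matrix of gray levels (`NA` = nodata).
#' @param offsets list of integer pairs `c(dy, dx)`; default `(0, 1)`.
#' @param symmetric logical; default `TRUE`.
#' @param n_levels gray-level count G; default `max(window) + 1`.
#' @return object of class `glcm`: list with `p` (G x G probability
#'   matrix), `n_levels`, `offsets`, `symmetric`, `n_pairs`.
#' @export
glcm <- function(window, offsets = list(c(0L, 1L)), symmetric = TRUE,
                 n_levels = NULL) {
  w <- as.matrix(window)
  G <- n_levels %||% (max(w, na.rm = TRUE) + 1L)
  assert_that(G >= 1, "window holds no valid gray level")
  counts <- matrix(0, G, G)
  nr <- nrow(w); nc <- ncol(w)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    if (max(1, 1 - dy) > min(nr, nr - dy) ||
        max(1, 1 - dx) > min(nc, nc - dx)) next
    r1 <- max(1, 1 - dy):min(nr, nr - dy)
    c1 <- max(1, 1 - dx):min(nc, nc - dx)
    a <- w[r1, c1, drop = FALSE]
    b <- w[r1 + dy, c1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(G - 1)),
                 factor(b[ok], levels = 0:(G - 1)))
    counts <- counts + unclass(tab)
  }
  if (symmetric) counts <- counts + t(counts)
  dimnames(counts) <- NULL
  n_pairs <- sum(counts)
  assert_that(n_pairs > 0, "no valid pixel pair in any offset direction")
  structure(list(p = counts / n_pairs, n_levels = G, offsets = offsets,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

haralick_feature_names <- function() {
  c("energy", "entropy", "correlation", "inverse_difference_moment",
    "inertia", "cluster_shade", "cluster_prominence", "haralick_correlation")
}

#' Haralick features of a co-occurrence matrix
#'
#' Computes the eight features used throughout the pipeline from a GLCM
#' `p(i, j)` with 0-based gray levels i, j:
#' energy `sum p^2`; entropy `-sum p log2 p` (bits); inertia (contrast)
#' `sum (i-j)^2 p`; inverse difference moment `sum p / (1 + (i-j)^2)`;
#' correlation `sum (i-mu_x)(j-mu_y) p / (sigma_x sigma_y)` with marginal
#' moments; cluster shade and prominence `sum ((i-mu_x)+(j-mu_y))^{3,4} p`;
#' Haralick correlation `(sum ij p - mu_t^2) / sigma_t^2` where `mu_t` and
#' `sigma_t` are the mean and (population) standard deviation of the G
#' marginal row sums, the convention of the common remote-sensing toolbox
#' lineage (`hc_variant = "marginal_sums"`); `hc_variant = "f3"` instead
#' returns the textbook index-weighted form, identical to `correlation`.
#' Degenerate zero-variance cases return 0 with a warning.
#'
#' @param m a [glcm()] object (or a bare probability matrix).
#' @param hc_variant `"marginal_sums"` (default) or `"f3"`.
#' @return named numeric vector of the 8 features.
#' @export
haralick_features <- function(m, hc_variant = c("marginal_sums", "f3")) {
  hc_variant <- match.arg(hc_variant)
  p <- if (inherits(m, "glcm")) m$p else as.matrix(m)
  G <- nrow(p)
  i <- matrix(0:(G - 1), G, G)          # row index
  j <- t(i)                             # column index
  energy <- sum(p^2)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  inertia <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  mu_x <- sum(i * p); mu_y <- sum(j * p)
  s_x <- sqrt(sum((i - mu_x)^2 * p)); s_y <- sqrt(sum((j - mu_y)^2 * p))
  if (s_x == 0 || s_y == 0) {
    warning("degenerate GLCM (zero marginal variance): correlation set to 0")
    correlation <- 0
  } else {
    correlation <- sum((i - mu_x) * (j - mu_y) * p) / (s_x * s_y)
  }
  shade <- sum(((i - mu_x) + (j - mu_y))^3 * p)
  prom  <- sum(((i - mu_x) + (j - mu_y))^4 * p)
  if (hc_variant == "f3") {
    hc <- correlation
  } else {
    px <- rowSums(p)
    mu_t <- mean(px)
    var_t <- mean((px - mu_t)^2)
    if (var_t < .Machine$double.eps) {
      warning("degenerate marginal row sums: Haralick correlation set to 0")
      hc <- 0
    } else {
      hc <- (sum(i * j * p) - mu_t^2) / var_t
    }
  }
  c(energy = energy, entropy = entropy, correlation = correlation,
    inverse_difference_moment = idm, inertia = inertia,
    cluster_shade = shade, cluster_prominence = prom,
    haralick_correlation = hc)
}

# Summed-area table box sum of matrix M over the window
# rows [r+a, r+b] x cols [c+e, c+f] (relative bounds), truncated at the
# image border.  Returns a matrix of the same shape.
box_sum <- function(M, a, b, e, f) {
  nr <- nrow(M); nc <- ncol(M)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- M
  S <- apply(S, 2, cumsum)              # (nr+1) x (nc+1), cumsum down rows
  S <- t(apply(S, 1, cumsum))           # then across columns
  ri <- seq_len(nr); ci <- seq_len(nc)
  r_hi <- pmin(ri + b, nr) + 1; r_lo <- pmax(ri + a - 1, 0) + 1
  c_hi <- pmin(ci + f, nc) + 1; c_lo <- pmax(ci + e - 1, 0) + 1
  S[r_hi, c_hi] - S[r_lo, c_hi] - S[r_hi, c_lo] + S[r_lo, c_lo]
}

#' Sliding-window Haralick texture images
#'
#' For every pixel, builds the GLCM of its `(2 radius + 1)^2` neighbourhood
#' (edge windows truncated at the image border, nodata pixels excluded from
#' pairs) and evaluates the eight Haralick features.  Implemented with
#' summed-area tables over the G^2 co-occurrence indicator planes, so the
#' cost is linear in the pixel count.
#'
#' @param raster a [raster_grid()] of continuous values, or an already
#'   quantized integer raster if `quantized = TRUE`.
#' @param radius window radius in pixels (default 2: a 5x5 window).
#' @param offsets list of `(dy, dx)` integer offsets (default `(0, 1)`).
#' @param n_levels gray levels after quantization (default 8).
#' @param value_range quantization range passed to [quantize()].
#' @param symmetric symmetric pair counting (default `TRUE`).
#' @param quantized set `TRUE` if `raster` already holds integer levels.
#' @return named list of eight [raster_grid()]s (feature images) sharing
#'   the input geometry.
#' @export
texture_image <- function(raster, radius = 2, offsets = list(c(0L, 1L)),
                          n_levels = 8, value_range = NULL,
                          symmetric = TRUE, quantized = FALSE) {
  is_rg <- inherits(raster, "raster_grid")
  vals <- if (is_rg) raster$values else as.matrix(raster)
  assert_that(nrow(vals) >= 2 && ncol(vals) >= 2, "raster smaller than 2x2")
  q <- if (quantized) vals else {
    qq <- quantize(raster, n_levels = n_levels, value_range = value_range)
    if (is_rg) qq$values else qq
  }
  G <- if (quantized) max(q, na.rm = TRUE) + 1 else n_levels
  nr <- nrow(q); nc <- ncol(q)
  valid <- !is.na(q)
  q0 <- q; q0[!valid] <- -1     # sentinel outside every level

  # window pair counts per ordered level pair (i, j), accumulated offsets
  C <- vector("list", G * G)
  for (k in seq_along(C)) C[[k]] <- matrix(0, nr, nc)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    # shifted copy: sh[r, c] = q0[r + dy, c + dx] (outside image = -1)
    sh <- matrix(-1, nr, nc)
    r_src <- max(1, 1 + dy):min(nr, nr + dy)
    c_src <- max(1, 1 + dx):min(nc, nc + dx)
    sh[r_src - dy, c_src - dx] <- q0[r_src, c_src]
    # first pixel of an in-window pair must lie in the offset-shrunk box
    a <- -radius + max(0, -dy); b <- radius - max(0, dy)
    e <- -radius + max(0, -dx); f <- radius - max(0, dx)
    for (i in 0:(G - 1)) {
      Ai <- (q0 == i)
      for (j in 0:(G - 1)) {
        P <- Ai & (sh == j)
        if (!any(P)) next
        k <- i * G + j + 1
        C[[k]] <- C[[k]] + box_sum(P + 0, a, b, e, f)
      }
    }
  }
  if (symmetric) {
    Cs <- vector("list", G * G)
    for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
      Cs[[i * G + j + 1]] <- C[[i * G + j + 1]] + C[[j * G + i + 1]]
    }
    C <- Cs
  }
  Ntot <- Reduce(`+`, C)
  ok <- valid & Ntot > 0
  Ninv <- ifelse(ok, 1 / Ntot, 0)

  zero <- matrix(0, nr, nc)
  energy <- zero; entropy <- zero; inertia <- zero; idm <- zero
  mu_x <- zero; mu_y <- zero; e_ij <- zero
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- C[[i * G + j + 1]] * Ninv
    energy <- energy + p * p
    entropy <- entropy - ifelse(p > 0, p * log2(p), 0)
    inertia <- inertia + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    mu_x <- mu_x + i * p
    mu_y <- mu_y + j * p
    e_ij <- e_ij + i * j * p
  }
  sxx <- zero; syy <- zero; shade <- zero; prom <- zero
  px <- vector("list", G)
  for (i in 0:(G - 1)) px[[i + 1]] <- zero
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- C[[i * G + j + 1]] * Ninv
    sxx <- sxx + (i - mu_x)^2 * p
    syy <- syy + (j - mu_y)^2 * p
    d <- (i - mu_x) + (j - mu_y)
    shade <- shade + d^3 * p
    prom <- prom + d^4 * p
    px[[i + 1]] <- px[[i + 1]] + p
  }
  sx <- sqrt(pmax(sxx, 0)); sy <- sqrt(pmax(syy, 0))
  nd <- sx > 0 & sy > 0
  correlation <- zero
  correlation[nd] <- (e_ij[nd] - mu_x[nd] * mu_y[nd]) / (sx[nd] * sy[nd])
  mu_t <- Reduce(`+`, px) / G
  var_t <- Reduce(`+`, lapply(px, function(v) (v - mu_t)^2)) / G
  hc <- zero
  hd <- var_t > .Machine$double.eps
  hc[hd] <- (e_ij[hd] - mu_t[hd]^2) / var_t[hd]

  feats <- list(energy = energy, entropy = entropy, correlation = correlation,
                inverse_difference_moment = idm, inertia = inertia,
                cluster_shade = shade, cluster_prominence = prom,
                haralick_correlation = hc)
  lapply(feats, function(m) {
    m[!ok] <- NA_real_
    if (is_rg) raster_grid(m, x0 = raster$x0, y0 = raster$y0,
                           cell = raster$cell, crs = raster$crs) else m
  })
}

#' Plot means of texture feature images
#'
#' Average of every feature image over the valid pixels whose centres fall
#' inside the (strip-trimmed) plot polygon.
#'
#' @param features named list of feature [raster_grid()]s (from
#'   [texture_image()]).
#' @param polygon vertex matrix or plot rectangle row.
#' @param excluded_strip_m strip removed from the low-y plot end (m).
#' @return named numeric vector (one value per feature).
#' @export
plot_texture_means <- function(features, polygon, excluded_strip_m = 1.5) {
  if (is.data.frame(polygon)) polygon <- plot_polygon(polygon)
  out <- vapply(features, function(r) {
    v <- rg_extract_polygon(r, polygon, strip_m = excluded_strip_m)
    assert_that(length(v) > 0, "no valid texture pixels inside the plot")
    mean(v)
  }, numeric(1))
  names(out) <- names(features)
  out
}
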