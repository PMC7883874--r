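# Independent brute-force oracles, kept deliberately naive: explicit loops
# and direct formula evaluation, no shared code with the package internals.

# Co-occurrence probabilities by enumerating every pixel pair.
brute_glcm <- function(window, offsets = list(c(0L, 1L)), symmetric = TRUE,
                       n_levels = max(window, na.rm = TRUE) + 1) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(window); nc <- ncol(window)
  for (off in offsets) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- window[r, c]; b <- window[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      if (symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts / sum(counts)
}

# All eight features by explicit double sums over the GLCM.
brute_haralick <- function(p) {
  G <- nrow(p)
  energy <- 0; entropy <- 0; inertia <- 0; idm <- 0
  mu_x <- 0; mu_y <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    v <- p[i + 1, j + 1]
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log2(v)
    inertia <- inertia + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    mu_x <- mu_x + i * v
    mu_y <- mu_y + j * v
  }
  sxx <- 0; syy <- 0; sxy <- 0; shade <- 0; prom <- 0; eij <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    v <- p[i + 1, j + 1]
    sxx <- sxx + (i - mu_x)^2 * v
    syy <- syy + (j - mu_y)^2 * v
    sxy <- sxy + (i - mu_x) * (j - mu_y) * v
    shade <- shade + ((i - mu_x) + (j - mu_y))^3 * v
    prom <- prom + ((i - mu_x) + (j - mu_y))^4 * v
    eij <- eij + i * j * v
  }
  correlation <- if (sxx == 0 || syy == 0) 0 else sxy / sqrt(sxx * syy)
  px <- rowSums(p)
  mu_t <- mean(px)
  var_t <- mean((px - mu_t)^2)
  hc <- if (var_t < .Machine$double.eps) 0 else (eij - mu_t^2) / var_t
  c(energy = energy, entropy = entropy, correlation = correlation,
    inverse_difference_moment = idm, inertia = inertia,
    cluster_shade = shade, cluster_prominence = prom,
    haralick_correlation = hc)
}

# Distribution metrics by direct sums and a full sort.
brute_csh_metrics <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  sk <- if (m2 == 0) 0 else (sum((v - m)^3) / n) / m2^1.5
  ku <- if (m2 == 0) 0 else (sum((v - m)^4) / n) / m2^2 - 3
  # type-7 quantile by hand: h = (n-1)p + 1 on the sorted sample
  q7 <- function(p) {
    s <- sort(v)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  rel <- if (max(v) == min(v)) 0 else (m - min(v)) / (max(v) - min(v))
  c(mean = m, min = min(v), max = max(v), median = q7(0.5),
    variance = sum((v - m)^2) / (n - 1), sd = sqrt(sum((v - m)^2) / (n - 1)),
    range = max(v) - min(v), skewness = sk, kurtosis = ku, relief = rel,
    p25 = q7(0.25), p75 = q7(0.75), p90 = q7(0.90), p95 = q7(0.95))
}

# Kruskal-Wallis H with tie correction, from first principles.
brute_kruskal_h <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  groups <- factor(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Masked zonal mean by looping over every cell centre.
brute_zonal_mean <- function(r, poly, strip = 0) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(r$values))) for (j in seq_len(ncol(r$values))) {
    cx <- r$x0 + (j - 0.5) * r$cell
    cy <- r$y0 + (i - 0.5) * r$cell
    if (is.na(r$values[i, j])) next
    if (!point_in_polygon(cx, cy, poly)) next
    if (cy < min(poly[, 2]) + strip) next
    tot <- tot + r$values[i, j]; n <- n + 1
  }
  if (n == 0) NA_real_ else tot / n
}
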