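# Internal 3D array helpers: boundary-aware index maps and separable
# convolution along one axis. All filters in the package are built on these,
# so boundary handling is defined in exactly one place:
#   "symmetric": mirror with edge repetition (a b c | c b a), the default;
#   "periodic":  circular wrap-around.

reflect_index <- function(i, n, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  if (n == 1L) return(rep(1L, length(i)))
  if (mode == "periodic") return(((i - 1L) %% n) + 1L)
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Correlate `a` with kernel `k` along `axis`; k[center] sits on the output
# voxel. Vectorised as one shifted-slab multiply-add per kernel tap.
convolve_axis <- function(a, k, axis, center = (length(k) + 1L) %/% 2L,
                          mode = "symmetric") {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, dim = d)
  base <- seq_len(n)
  for (t in seq_along(k)) {
    if (k[t] == 0) next
    idx <- reflect_index(base + (t - center), n, mode)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + k[t] * shifted
  }
  out
}

# Sampled 1D Gaussian and its second derivative, on the voxel grid of one
# axis (physical units: sigma and spacing in mm). Unnormalised exact samples;
# `normalize` rescales to unit sum (used for smoothing, not for LoG).
gaussian_taps <- function(sigma_mm, spacing_mm, radius_sigmas = 4,
                          normalize = FALSE) {
  r <- max(1L, as.integer(ceiling(radius_sigmas * sigma_mm / spacing_mm)))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  if (normalize) g <- g / sum(g)
  g
}

gaussian_d2_taps <- function(sigma_mm, spacing_mm, radius_sigmas = 4) {
  r <- max(1L, as.integer(ceiling(radius_sigmas * sigma_mm / spacing_mm)))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  k <- g * (x^2 - sigma_mm^2) / sigma_mm^4
  # enforce a zero-sum kernel so constants map exactly to zero (the
  # truncated sampled second derivative has a tiny DC residual)
  k - mean(k)
}

# Separable Gaussian smoothing with physically scaled sigma (mm).
gaussian_smooth <- function(a, sigma_mm, spacing, mode = "symmetric") {
  if (sigma_mm <= 0) return(a)
  for (ax in 1:3) {
    k <- gaussian_taps(sigma_mm, spacing[ax], radius_sigmas = 3, normalize = TRUE)
    a <- convolve_axis(a, k, ax, mode = mode)
  }
  a
}

# Bounding box of TRUE voxels, expanded by `margin` voxels, clipped to grid.
mask_bbox <- function(voxels, margin = 0L) {
  d <- dim(voxels)
  w <- which(voxels, arr.ind = TRUE)
  lo <- pmax(1L, apply(w, 2, min) - margin)
  hi <- pmin(d, apply(w, 2, max) + margin)
  list(lo = lo, hi = hi)
}

crop_to_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# The 13 unique 3D voxel-offset directions (one per +/- pair).
DIRECTIONS_13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, , drop = FALSE])
})
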