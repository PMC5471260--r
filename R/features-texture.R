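#' Discretize in-mask intensities into gray levels
#'
#' Fixed-bin-width discretization anchored at the in-mask minimum:
#' `level(v) = floor((HU(v) - min) / bin_width) + 1`. Adding a constant to
#' all intensities therefore leaves the levels unchanged. A constant region
#' yields a single level (`ng = 1`), which is valid.
#'
#' @param volume a [voxel_volume()] (or any filtered image on the same grid).
#' @param mask an aligned [region_mask()] with >= 1 foreground voxel.
#' @param bin_width_hu positive bin width, in the image's intensity units
#'   (HU for unfiltered CT; filter-response units for filtered images).
#' @return A `discretized_region`: integer `levels` array on the mask
#'   bounding box (NA outside the mask), `ng`, `bin_width_hu`, `hu_min`,
#'   `spacing`.
#' @export
discretize <- function(volume, mask, bin_width_hu = 25) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  if (!is.numeric(bin_width_hu) || bin_width_hu <= 0)
    stop("bin_width_hu must be positive")
  bb <- mask_bbox(mask$voxels)
  m <- crop_to_bbox(mask$voxels, bb)
  a <- crop_to_bbox(volume$intensities, bb)
  x <- a[m]
  if (any(!is.finite(x)))
    stop("non-finite intensities inside the mask; cannot discretize")
  hu_min <- min(x)
  lev <- array(NA_integer_, dim(m))
  lev[m] <- as.integer(floor((a[m] - hu_min) / bin_width_hu)) + 1L
  structure(list(levels = lev, ng = max(lev, na.rm = TRUE),
                 bin_width_hu = bin_width_hu, hu_min = hu_min,
                 spacing = volume$spacing),
            class = "discretized_region")
}

# offset sub-array pair for direction (dx,dy,dz): returns list(a, b) of the
# overlapping slabs of `lev` such that b is a shifted by the offset.
.shift_pair <- function(lev, off) {
  d <- dim(lev)
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(NULL)
  r1 <- lo[1]:hi[1]; r2 <- lo[2]:hi[2]; r3 <- lo[3]:hi[3]
  list(a = lev[r1, r2, r3, drop = FALSE],
       b = lev[r1 + off[1], r2 + off[2], r3 + off[3], drop = FALSE])
}

# Symmetric, normalized GLCM for one direction; NULL when no voxel pair.
glcm_matrix <- function(disc, off) {
  sp <- .shift_pair(disc$levels, off)
  if (is.null(sp)) return(NULL)
  ok <- !is.na(sp$a) & !is.na(sp$b)
  if (!any(ok)) return(NULL)
  ng <- disc$ng
  counts <- tabulate(sp$a[ok] + (sp$b[ok] - 1L) * ng, nbins = ng * ng)
  counts <- matrix(counts, ng, ng)
  counts <- counts + t(counts)  # symmetric accumulation
  counts / sum(counts)
}

glcm_feature_names <- c(
  "autocorrelation", "cluster_prominence", "cluster_shade", "cluster_tendency",
  "contrast", "correlation", "difference_entropy", "dissimilarity", "energy",
  "entropy", "homogeneity", "inverse_difference_moment", "inverse_variance",
  "maximum_probability", "sum_average", "sum_entropy", "sum_variance")

glcm_features_one <- function(p) {
  ng <- nrow(p)
  ii <- row(p); jj <- col(p)
  pm <- rowSums(p)
  mu <- sum(seq_len(ng) * pm)
  sig2 <- sum((seq_len(ng) - mu)^2 * pm)
  s <- ii + jj - 2 * mu
  dif <- abs(ii - jj)
  psum <- as.numeric(tapply(p, ii + jj, sum))
  ks <- sort(unique(as.vector(ii + jj)))
  pdif <- as.numeric(tapply(p, dif, sum))
  sa <- sum(ks * psum)
  ent2 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  offd <- ii != jj
  c(autocorrelation = sum(ii * jj * p),
    cluster_prominence = sum(s^4 * p),
    cluster_shade = sum(s^3 * p),
    cluster_tendency = sum(s^2 * p),
    contrast = sum((ii - jj)^2 * p),
    correlation = if (sig2 > 0) (sum(ii * jj * p) - mu^2) / sig2 else NaN,
    difference_entropy = ent2(pdif),
    dissimilarity = sum(dif * p),
    energy = sum(p^2),
    entropy = ent2(p),
    homogeneity = sum(p / (1 + dif)),
    inverse_difference_moment = sum(p / (1 + (ii - jj)^2)),
    inverse_variance = if (any(offd)) sum(p[offd] / dif[offd]^2) else 0,
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = ent2(psum),
    sum_variance = sum((ks - sa)^2 * psum))
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Builds a symmetric, per-direction-normalized GLCM for each of the 13
#' unique 3D directions at the given voxel distance, computes 17 Haralick-
#' style features per direction, and averages each feature over the
#' directions that contain at least one voxel pair. `correlation` is NaN
#' (declared-undefined) on constant regions.
#'
#' @param disc a [discretize()]d region.
#' @param distance positive integer voxel distance (default 1).
#' @return Named numeric vector of 17 features.
#' @export
glcm_features <- function(disc, distance = 1L) {
  stopifnot(inherits(disc, "discretized_region"))
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1")
  per <- list()
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    p <- glcm_matrix(disc, DIRECTIONS_13[k, ] * distance)
    if (!is.null(p)) per[[length(per) + 1L]] <- glcm_features_one(p)
  }
  if (!length(per)) {
    warning("no voxel pair in any direction; GLCM features undefined")
    return(stats::setNames(rep(NaN, length(glcm_feature_names)),
                           glcm_feature_names))
  }
  colMeans(do.call(rbind, per))
}

# Zones: connected components of equal gray level (26- or 6-connectivity).
# Returns integer vector of zone sizes.
zone_sizes <- function(disc, connectivity = 26L) {
  lev <- disc$levels
  d <- dim(lev)
  idx <- array(0L, d)
  inm <- which(!is.na(lev))
  idx[inm] <- seq_along(inm)
  offs <- if (connectivity == 26L) DIRECTIONS_13 else
    matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, byrow = TRUE)
  efrom <- integer(0); eto <- integer(0)
  for (k in seq_len(nrow(offs))) {
    sp <- .shift_pair(lev, offs[k, ])
    si <- .shift_pair(idx, offs[k, ])
    if (is.null(sp)) next
    ok <- !is.na(sp$a) & !is.na(sp$b) & sp$a == sp$b
    if (!any(ok)) next
    efrom <- c(efrom, si$a[ok])
    eto <- c(eto, si$b[ok])
  }
  nv <- length(inm)
  if (!length(efrom)) return(rep(1L, nv))
  g <- igraph::make_graph(rbind(efrom, eto), n = nv, directed = FALSE)
  igraph::components(g)$csize
}

#' GLSZM size-zone variability
#'
#' Zones are 26-connected components of voxels sharing a gray level. With
#' `n(g, s)` zones of level `g` and size `s` and `Nz` zones in total, the
#' size-zone variability is `(1/Nz) * sum_s (sum_g n(g, s))^2` -- large when
#' many zones repeat the same size (a fragmented, heterogeneous region),
#' equal to 1 for a single homogeneous zone.
#'
#' @param disc a [discretize()]d region.
#' @param connectivity 26 (default) or 6.
#' @return A single numeric value.
#' @export
glszm_size_zone_variability <- function(disc, connectivity = 26L) {
  stopifnot(inherits(disc, "discretized_region"))
  sz <- zone_sizes(disc, connectivity)
  tab <- tabulate(sz)
  sum(tab^2) / length(sz)
}

#' Run-length (RLGL) features
#'
#' Decomposes the in-mask voxels into maximal same-level runs along each of
#' the 13 unique 3D directions and averages five run-length features over
#' directions: short-run emphasis, long-run emphasis, gray-level
#' non-uniformity, run-length non-uniformity, and run percentage.
#'
#' @param disc a [discretize()]d region.
#' @return Named numeric vector of 5 features.
#' @export
rlgl_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_region"))
  lev <- disc$levels
  d <- dim(lev)
  w <- which(!is.na(lev), arr.ind = TRUE)
  lv <- lev[w]
  np <- nrow(w)
  inside <- function(m) m[, 1] >= 1L & m[, 1] <= d[1] &
    m[, 2] >= 1L & m[, 2] <= d[2] & m[, 3] >= 1L & m[, 3] <= d[3]
  feats <- matrix(NA_real_, nrow(DIRECTIONS_13), 5L)
  for (k in seq_len(nrow(DIRECTIONS_13))) {
    off <- DIRECTIONS_13[k, ]
    prev <- sweep(w, 2L, off, `-`)
    okp <- inside(prev)
    same_prev <- rep(FALSE, np)
    same_prev[okp] <- { pl <- lev[prev[okp, , drop = FALSE]]
                        !is.na(pl) & pl == lv[okp] }
    starts <- which(!same_prev)
    cur <- w[starts, , drop = FALSE]
    slev <- lv[starts]
    len <- rep(1L, length(starts))
    active <- seq_along(starts)
    pos <- cur
    while (length(active)) {
      nxt <- sweep(pos[active, , drop = FALSE], 2L, off, `+`)
      okn <- inside(nxt)
      cont <- rep(FALSE, length(active))
      if (any(okn)) {
        nl <- lev[nxt[okn, , drop = FALSE]]
        cont[okn] <- !is.na(nl) & nl == slev[active][okn]
      }
      len[active[cont]] <- len[active[cont]] + 1L
      pos[active[cont], ] <- nxt[cont, , drop = FALSE]
      active <- active[cont]
    }
    nr <- length(starts)
    feats[k, ] <- c(sum(1 / len^2) / nr,
                    sum(as.numeric(len)^2) / nr,
                    sum(tabulate(slev)^2) / nr,
                    sum(tabulate(len)^2) / nr,
                    nr / np)
  }
  stats::setNames(colMeans(feats),
                  c("short_run_emphasis", "long_run_emphasis",
                    "gray_level_nonuniformity", "run_length_nonuniformity",
                    "run_percentage"))
}
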