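# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit enumeration, no shared code with R/) so they
# can arbitrate the vectorised implementations.

# 3D ball mask on an n^3 grid
make_ball_mask <- function(n, radius, spacing = c(1, 1, 1)) {
  cx <- ((1:n) - (n + 1) / 2) * spacing[1]
  cy <- ((1:n) - (n + 1) / 2) * spacing[2]
  cz <- ((1:n) - (n + 1) / 2) * spacing[3]
  m <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`) <= radius^2
  region_mask(array(m, c(n, n, n)), spacing)
}

# random small labelled region: list(volume, mask, disc-compatible levels)
random_region <- function(dims, ng, fill = 0.8) {
  m <- array(stats::runif(prod(dims)) < fill, dims)
  if (!any(m)) m[1] <- TRUE
  lev <- array(NA_integer_, dims)
  lev[m] <- sample.int(ng, sum(m), replace = TRUE)
  # ensure level 1 present so levels are 1..max contiguous after remap
  lev[m][1] <- 1L
  lev[m] <- as.integer(factor(lev[m]))
  list(mask = m, levels = lev, ng = max(lev, na.rm = TRUE))
}

disc_from_levels <- function(lev, ng, spacing = c(1, 1, 1)) {
  structure(list(levels = lev, ng = ng, bin_width_hu = 1, hu_min = 0,
                 spacing = spacing),
            class = "discretized_region")
}

# volume/mask pair whose 1-HU-wide discretization reproduces given levels
volume_from_levels <- function(lev, spacing = c(1, 1, 1)) {
  a <- array(0, dim(lev))
  a[!is.na(lev)] <- as.numeric(lev[!is.na(lev)])
  list(volume = voxel_volume(a, spacing),
       mask = region_mask(!is.na(lev), spacing))
}

all_offsets_13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
                (g$dz == 0 & g$dy == 0 & g$dx > 0), ])
})

# oracle: symmetric normalized GLCM by explicit voxel-pair enumeration
oracle_glcm <- function(lev, off, ng) {
  d <- dim(lev)
  cnt <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    p <- c(i, j, k) + off
    if (any(p < 1) || any(p > d)) next
    b <- lev[p[1], p[2], p[3]]
    if (is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# oracle: zone sizes by recursive flood fill (26- or 6-connected)
oracle_zone_sizes <- function(lev, connectivity = 26L) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  sizes <- integer(0)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    g <- lev[v[1], v[2], v[3]]
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        lq <- lev[q[1], q[2], q[3]]
        if (is.na(lq) || lq != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# oracle: run-length list (level, length) for one direction, by walking
oracle_runs <- function(lev, off) {
  d <- dim(lev)
  inb <- function(p) all(p >= 1) && all(p <= d)
  runs <- NULL
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    g <- lev[v[1], v[2], v[3]]
    prev <- v - off
    if (inb(prev) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == g) next
    len <- 1L
    p <- v + off
    while (inb(p) && !is.na(lev[p[1], p[2], p[3]]) &&
           lev[p[1], p[2], p[3]] == g) {
      len <- len + 1L
      p <- p + off
    }
    runs <- rbind(runs, c(g, len))
  }
  runs
}

oracle_rlgl <- function(lev) {
  np <- sum(!is.na(lev))
  f <- matrix(NA_real_, nrow(all_offsets_13), 5)
  for (k in seq_len(nrow(all_offsets_13))) {
    runs <- oracle_runs(lev, all_offsets_13[k, ])
    nr <- nrow(runs)
    g <- runs[, 1]; l <- runs[, 2]
    f[k, ] <- c(sum(1 / l^2) / nr, sum(l^2) / nr,
                sum(table(g)^2) / nr, sum(table(l)^2) / nr, nr / np)
  }
  colMeans(f)
}

# oracle: AUC by exhaustive pair counting (wins + half ties)
oracle_auc <- function(values, labels) {
  v1 <- values[labels == 1]; v0 <- values[labels == 0]
  s <- 0
  for (a in v1) for (b in v0) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(v1) * length(v0))
}

# oracle: BH step-up by the literal definition
# q(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(1, min(m * p[j] / r[j]))
  }, numeric(1))
}

# one-row semantic record with overridable scores
semantic_record <- function(...) {
  base <- list(subject_id = "S1", cavitation = 0L, air_bronchogram = 0L,
               calcification = 0L, texture = 3L, border_definition = 1L,
               contour = 1L, lobulation = 1L, spiculation = 1L, concavity = 1L)
  ov <- list(...)
  base[names(ov)] <- lapply(ov, as.integer)
  as.data.frame(base, stringsAsFactors = FALSE)
}
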