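test_that("discretization follows the anchored floor rule and shift invariance", {
  lev <- array(NA_real_, c(4, 1, 1))
  v <- voxel_volume(array(c(0, 24.9, 25, 60), c(4, 1, 1)))
  m <- region_mask(array(1, c(4, 1, 1)))
  d <- discretize(v, m, 25)
  expect_equal(as.vector(d$levels), c(1, 1, 2, 3))
  expect_equal(d$ng, 3)

  vconst <- voxel_volume(array(-100, c(3, 1, 1)))
  mc <- region_mask(array(1, c(3, 1, 1)))
  dc <- discretize(vconst, mc, 25)
  expect_equal(dc$ng, 1)

  vshift <- voxel_volume(v$intensities + 137.5)
  expect_equal(discretize(vshift, m, 25)$levels, d$levels)
})

test_that("single-voxel volume and rotation invariance of shape features", {
  one <- region_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)))
  expect_equal(unname(shape_features(one)["volume"]), 1)

  set.seed(21)
  rr <- random_region(c(6, 5, 4), 2)
  m <- region_mask(rr$mask)
  rot <- region_mask(aperm(rr$mask[, , dim(rr$mask)[3]:1], c(1, 3, 2)))
  f1 <- shape_features(m)
  f2 <- shape_features(rot)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("sphericity never exceeds 1 + eps and decreases with perturbation", {
  set.seed(31)
  for (i in 1:8) {
    rr <- random_region(c(5, 5, 5), 2, fill = 0.6)
    psi <- unname(shape_features(region_mask(rr$mask))["sphericity"])
    expect_lte(psi, 1.01)
  }
  # increasingly perturbed star-convex phantoms
  psis <- sapply(c(1, 2, 3), function(sc) {
    ph <- build_phantom(phenotype_spec(semantic_record(spiculation = sc),
                                       seed = 5))
    unname(shape_features(ph$mask)["sphericity"])
  })
  expect_true(all(diff(psis) < 0))
})

test_that("intensity statistics match closed forms and a direct oracle", {
  v <- voxel_volume(array(c(1, 2, 3, 4, 5, 0), c(6, 1, 1)))
  m <- region_mask(array(c(1, 1, 1, 1, 1, 0), c(6, 1, 1)))
  s <- intensity_statistics(v, m)
  expect_equal(unname(s[c("mean", "median", "range")]), c(3, 3, 4))
  expect_equal(unname(s["standard_deviation"]), sqrt(2), tolerance = 1e-12)

  vs <- voxel_volume(array(c(-4, 0, 4), c(3, 1, 1)))
  ms <- region_mask(array(1, c(3, 1, 1)))
  expect_equal(unname(intensity_statistics(vs, ms)["skewness"]), 0)

  set.seed(41)
  x <- rnorm(200, sd = 150)
  vr <- voxel_volume(array(x, c(200, 1, 1)))
  mr <- region_mask(array(1, c(200, 1, 1)))
  sr <- intensity_statistics(vr, mr)
  mu <- sum(x) / 200
  m2 <- sum((x - mu)^2) / 200
  oracle <- c(energy = sum(x^2), mean = mu,
              mean_absolute_deviation = sum(abs(x - mu)) / 200,
              root_mean_square = sqrt(sum(x^2) / 200),
              skewness = (sum((x - mu)^3) / 200) / m2^1.5,
              kurtosis = (sum((x - mu)^4) / 200) / m2^2 - 3,
              standard_deviation = sqrt(m2))
  expect_equal(sr[names(oracle)], oracle, tolerance = 1e-10)

  const <- voxel_volume(array(5, c(4, 1, 1)))
  mm <- region_mask(array(1, c(4, 1, 1)))
  expect_message(sc <- intensity_statistics(const, mm), "undefined")
  expect_true(is.nan(sc[["skewness"]]) && is.nan(sc[["kurtosis"]]))
})

test_that("GLCM trivial cases and label-flip symmetries hold", {
  dc <- disc_from_levels(array(1L, c(3, 3, 3)), 1L)
  f <- glcm_features(dc)
  expect_equal(unname(f[c("energy", "entropy", "contrast")]), c(1, 0, 0))
  expect_true(is.nan(f[["correlation"]]))

  set.seed(51)
  rr <- random_region(c(4, 4, 3), 3)
  f1 <- glcm_features(disc_from_levels(rr$levels, rr$ng))
  flip <- rr$levels
  flip[!is.na(flip)] <- rr$ng + 1L - flip[!is.na(flip)]
  f2 <- glcm_features(disc_from_levels(flip, rr$ng))
  for (nm in c("energy", "entropy", "contrast", "dissimilarity",
               "homogeneity", "maximum_probability"))
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12, label = nm)
})

test_that("GLCM matches exhaustive pair enumeration on random small regions", {
  set.seed(61)
  for (rep in 1:6) {
    dims <- sample(2:4, 3, replace = TRUE)
    rr <- random_region(dims, sample(2:4, 1))
    dc <- disc_from_levels(rr$levels, rr$ng)
    per_dir <- list()
    for (k in seq_len(nrow(all_offsets_13))) {
      p <- oracle_glcm(rr$levels, all_offsets_13[k, ], rr$ng)
      if (!is.null(p)) {
        # oracle features computed with naive loops over the matrix
        ii <- row(p); jj <- col(p)
        pm <- rowSums(p); mu <- sum(seq_len(rr$ng) * pm)
        per_dir[[length(per_dir) + 1L]] <- c(
          autocorrelation = sum(ii * jj * p),
          contrast = sum((ii - jj)^2 * p),
          energy = sum(p^2),
          cluster_shade = sum((ii + jj - 2 * mu)^3 * p),
          sum_entropy = {
            ps <- tapply(p, ii + jj, sum); ps <- ps[ps > 0]
            -sum(ps * log2(ps)) })
      }
    }
    oracle <- colMeans(do.call(rbind, per_dir))
    got <- glcm_features(dc)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("GLSZM size-zone variability matches hand values and flood-fill", {
  expect_equal(glszm_size_zone_variability(
    disc_from_levels(array(1L, c(3, 3, 3)), 1L)), 1)

  # 8 isolated single-voxel zones in a 5x5x1 slab: SZV = 8^2 / 8 = 8
  lev <- array(NA_integer_, c(5, 5, 1))
  pos <- expand.grid(c(1, 3, 5), c(1, 3, 5))[-5, ]  # 8 non-adjacent cells
  for (r in 1:8) lev[pos[r, 1], pos[r, 2], 1] <- 1L
  expect_equal(glszm_size_zone_variability(disc_from_levels(lev, 1L)), 8)

  # checkerboard: two levels, 26-connectivity joins same-level diagonals
  chk <- array(NA_integer_, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) chk[i, j, 1] <- 1L + (i + j) %% 2L
  sizes_o <- oracle_zone_sizes(chk, 26L)
  expect_equal(glszm_size_zone_variability(disc_from_levels(chk, 2L)),
               sum(table(sizes_o)^2) / length(sizes_o))

  set.seed(71)
  for (rep in 1:6) {
    rr <- random_region(sample(2:4, 3, TRUE), sample(2:4, 1), fill = 0.7)
    got <- glszm_size_zone_variability(disc_from_levels(rr$levels, rr$ng))
    sz <- oracle_zone_sizes(rr$levels, 26L)
    expect_equal(got, sum(table(sz)^2) / length(sz), tolerance = 1e-10)
  }
})

test_that("run-length features match hand evaluation and the run oracle", {
  # constant 1x1xN line: along the line direction one run of length N
  lev <- array(1L, c(1, 1, 6))
  f <- rlgl_features(disc_from_levels(lev, 1L))
  runs_z <- oracle_runs(lev, c(0, 0, 1))
  expect_equal(nrow(runs_z), 1)
  expect_equal(runs_z[1, 2], 6)  # run percentage 1/6 in that direction
  expect_equal(f, stats::setNames(oracle_rlgl(lev), names(f)),
               tolerance = 1e-12)

  # fully alternating levels: all runs length 1, SRE = 1 in that direction
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  runs_x <- oracle_runs(alt, c(1, 0, 0))
  expect_true(all(runs_x[, 2] == 1))
  fa <- rlgl_features(disc_from_levels(alt, 2L))
  expect_equal(unname(fa), oracle_rlgl(alt), tolerance = 1e-10)

  set.seed(81)
  for (rep in 1:6) {
    rr <- random_region(sample(2:4, 3, TRUE), sample(2:4, 1), fill = 0.8)
    expect_equal(rlgl_features(disc_from_levels(rr$levels, rr$ng)),
                 stats::setNames(oracle_rlgl(rr$levels),
                                 names(rlgl_features(disc_from_levels(rr$levels, rr$ng)))),
                 tolerance = 1e-10)
  }
})

test_that("texture features are invariant to HU shifts and translations", {
  set.seed(91)
  rr <- random_region(c(5, 4, 4), 3, fill = 0.9)
  vm <- volume_from_levels(rr$levels)
  base <- extract_features(vm$volume, vm$mask, bin_width_hu = 1)

  shifted_vol <- voxel_volume(vm$volume$intensities + 500)
  shift_feats <- extract_features(shifted_vol, vm$mask, bin_width_hu = 1)
  tex <- grep("glcm|glszm|rlgl|entropy", names(base), value = TRUE)
  expect_equal(shift_feats[tex], base[tex], tolerance = 1e-12)

  # translate volume+mask inside a larger grid
  big_v <- array(0, c(9, 8, 8)); big_m <- array(FALSE, c(9, 8, 8))
  big_v[2:6, 2:5, 2:5] <- vm$volume$intensities
  big_m[2:6, 2:5, 2:5] <- vm$mask$voxels
  t1 <- extract_features(voxel_volume(big_v), region_mask(big_m), bin_width_hu = 1)
  big_v2 <- array(0, c(9, 8, 8)); big_m2 <- array(FALSE, c(9, 8, 8))
  big_v2[4:8, 3:6, 4:7] <- vm$volume$intensities
  big_m2[4:8, 3:6, 4:7] <- vm$mask$voxels
  t2 <- extract_features(voxel_volume(big_v2), region_mask(big_m2), bin_width_hu = 1)
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("feature inventory: 48 original features, 35 per filtered image", {
  ph <- build_phantom(phenotype_spec(semantic_record(), seed = 3),
                      grid_shape = c(40, 40, 40))
  fv <- extract_features(ph$volume, ph$mask)
  expect_length(fv, 48)
  fam <- sub("^orig\\.([a-z]+)\\..*$", "\\1", names(fv))
  expect_equal(unname(table(fam)[c("shape", "stats", "glcm", "glszm", "rlgl")]),
               c(13L, 12L, 17L, 1L, 5L), ignore_attr = TRUE)

  cfg <- filter_bank_config(log_sigmas_mm = 2, subbands = c("LLL", "HHH"))
  fv3 <- extract_features(ph$volume, ph$mask, cfg)
  expect_length(fv3, 48 + 3 * 35)
  expect_identical(fv3, extract_features(ph$volume, ph$mask, cfg))  # determinism
})
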