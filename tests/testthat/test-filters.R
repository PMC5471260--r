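test_that("LoG is zero on constants, linear, and matches the closed form on an impulse", {
  const <- voxel_volume(array(7, c(16, 16, 16)))
  r <- log_filter(const, 2)
  expect_lt(max(abs(r$intensities)), 1e-9)

  set.seed(3)
  v <- voxel_volume(array(rnorm(16^3), c(16, 16, 16)))
  r1 <- log_filter(v, 2)$intensities
  r3 <- log_filter(voxel_volume(3 * v$intensities, v$spacing), 2)$intensities
  expect_equal(r3, 3 * r1, tolerance = 1e-10)

  # impulse response vs the sampled continuous 3D LoG kernel
  n <- 33L; c0 <- 17L; sigma <- 2
  imp <- array(0, c(n, n, n)); imp[c0, c0, c0] <- 1
  resp <- log_filter(voxel_volume(imp), sigma)$intensities
  g <- function(x) exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  g2 <- function(x) g(x) * (x^2 - sigma^2) / sigma^4
  coords <- (1:n) - c0
  for (p in list(c(0, 0, 0), c(1, 0, 0), c(2, 3, 1), c(-5, 2, -4), c(7, 0, 0))) {
    x <- p[1]; y <- p[2]; z <- p[3]
    expected <- g2(x) * g(y) * g(z) + g(x) * g2(y) * g(z) + g(x) * g(y) * g2(z)
    expect_equal(resp[c0 + x, c0 + y, c0 + z], expected, tolerance = 1e-6,
                 label = paste("LoG impulse at", paste(p, collapse = ",")))
  }
  expect_error(log_filter(v, -1), "positive")
})

test_that("LoG sigma is interpreted in mm through anisotropic spacing", {
  # same physical impulse response sampled on two grids
  n <- 41L; c0 <- 21L
  imp <- array(0, c(n, n, n)); imp[c0, c0, c0] <- 1
  iso <- log_filter(voxel_volume(imp, c(1, 1, 1)), 3)$intensities
  ani <- log_filter(voxel_volume(imp, c(1, 1, 1.5)), 3)$intensities
  # voxel at physical z = 3 mm: index offset 3 (iso) vs 2 (1.5 mm slices);
  # responses differ only by the voxel-volume scaling of the convolution
  expect_equal(ani[c0 + 2, c0, c0 + 2] / 1.5, iso[c0 + 2, c0, c0 + 3],
               tolerance = 1e-8)
})

test_that("wavelet sub-bands: DC handling, count, determinism, Parseval", {
  const <- voxel_volume(array(5, c(12, 12, 12)))
  sb <- wavelet_subbands(const)
  expect_length(sb, 8)
  for (nm in names(sb)) {
    if (nm == "wv.LLL") {
      expect_equal(stats::sd(sb[[nm]]$intensities), 0, tolerance = 1e-10)
      expect_gt(abs(mean(sb[[nm]]$intensities)), 1)  # scaled DC, not zero
    } else {
      expect_lt(max(abs(sb[[nm]]$intensities)), 1e-9)
    }
  }

  set.seed(5)
  v <- voxel_volume(array(rnorm(10^3), c(10, 10, 10)))
  a <- wavelet_subbands(v)
  b <- wavelet_subbands(v)
  expect_identical(lapply(a, `[[`, "intensities"), lapply(b, `[[`, "intensities"))

  # Parseval for the undecimated transform with an orthonormal kernel on a
  # periodic volume: sum of sub-band energies / 8 = input energy
  sbp <- wavelet_subbands(v, mode = "periodic")
  e_in <- sum(v$intensities^2)
  e_out <- sum(vapply(sbp, function(s) sum(s$intensities^2), numeric(1)))
  expect_equal(e_out / 8, e_in, tolerance = 1e-8)
  expect_error(wavelet_subbands(v, kernel = "nosuch"), "unknown wavelet")
})

test_that("filter bank has the configured inventory and is shift-equivariant", {
  set.seed(9)
  v <- voxel_volume(array(rnorm(14^3), c(14, 14, 14)))
  fb <- apply_filter_bank(v)
  expect_length(fb, 13)  # 5 LoG + 8 sub-bands
  expect_named(fb, c(paste0("log.sigma", 1:5),
                     paste0("wv.", c("LLL", "LLH", "LHL", "LHH",
                                     "HLL", "HLH", "HHL", "HHH"))))
  one <- apply_filter_bank(v, filter_bank_config(log_sigmas_mm = numeric(0),
                                                 subbands = "LLL"))
  expect_length(one, 1)
  expect_error(filter_bank_config(subbands = "LHX"), "unknown sub-band")
  expect_error(filter_bank_config(log_sigmas_mm = c(2, 1)), "increasing")

  # translation equivariance on interior voxels: content far from the
  # boundary band, whole pattern shifted by one voxel along x
  set.seed(10)
  block <- array(rnorm(6^3), c(6, 6, 6))
  v0 <- array(0, c(30, 30, 30)); v0[13:18, 13:18, 13:18] <- block
  v1 <- array(0, c(30, 30, 30)); v1[14:19, 13:18, 13:18] <- block
  f0 <- log_filter(voxel_volume(v0), 1.5)$intensities
  f1 <- log_filter(voxel_volume(v1), 1.5)$intensities
  core <- 9:22
  expect_equal(f1[core + 1, core, core], f0[core, core, core],
               tolerance = 1e-10)
})
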