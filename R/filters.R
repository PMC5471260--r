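#' Filter bank configuration
#'
#' Configures the filtered-image set on which filtered radiomic features are
#' computed: one Laplacian-of-Gaussian (LoG) response per scale, plus the 8
#' sub-bands of a single-level stationary (undecimated) separable 3D wavelet
#' transform. Sub-band names use one letter per axis in (x, y, z) order:
#' first letter = filter applied along x. Defaults follow common radiomics
#' practice: LoG scales 1..5 mm, coiflet-1 kernel, all 8 sub-bands.
#'
#' @param log_sigmas_mm strictly increasing positive LoG scales in mm
#'   (may be empty).
#' @param wavelet wavelet kernel name; currently `"coif1"` or `"haar"`.
#' @param subbands subset of `c("LLL","LLH","LHL","LHH","HLL","HLH","HHL","HHH")`.
#' @return A `filter_bank_config` list.
#' @export
filter_bank_config <- function(log_sigmas_mm = c(1, 2, 3, 4, 5),
                               wavelet = "coif1",
                               subbands = c("LLL", "LLH", "LHL", "LHH",
                                            "HLL", "HLH", "HHL", "HHH")) {
  log_sigmas_mm <- as.numeric(log_sigmas_mm)
  if (length(log_sigmas_mm)) {
    if (any(!is.finite(log_sigmas_mm)) || any(log_sigmas_mm <= 0))
      stop("log_sigmas_mm must be positive and finite")
    if (is.unsorted(log_sigmas_mm, strictly = TRUE))
      stop("log_sigmas_mm must be strictly increasing")
  }
  all8 <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  subbands <- as.character(subbands)
  bad <- setdiff(subbands, all8)
  if (length(bad)) stop("unknown sub-band name(s): ", paste(bad, collapse = ", "))
  wavelet_kernels(wavelet)  # validates the name
  structure(list(log_sigmas_mm = log_sigmas_mm, wavelet = wavelet,
                 subbands = subbands),
            class = "filter_bank_config")
}

# Orthonormal decomposition filter pairs (low, high). coif1 taps are the
# standard coiflet-1 coefficients (sum of lo = sqrt(2)).
wavelet_kernels <- function(name) {
  switch(name,
         coif1 = list(
           lo = c(-0.015655728135791993, -0.07273261951252645,
                  0.3848648468648578, 0.8525720202116004,
                  0.3378976624574818, -0.07273261951252645),
           hi = c(0.07273261951252645, 0.3378976624574818,
                  -0.8525720202116004, 0.3848648468648578,
                  0.07273261951252645, -0.015655728135791993)),
         haar = list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2)),
         stop("unknown wavelet kernel '", name, "'"))
}

#' Laplacian-of-Gaussian filter
#'
#' Band-pass blob-detection filter at physical scale `sigma_mm`. The 3D LoG
#' is separable as a sum of three products of 1D Gaussian / second-derivative
#' kernels; each 1D kernel is the exactly sampled continuous function on the
#' voxel grid (sigma in mm, converted per-axis by the spacing), truncated at
#' 6 sigma, and the response is scaled by the voxel volume so it approximates
#' the continuous convolution integral. Boundaries use symmetric mirroring.
#'
#' @param volume a [voxel_volume()] with finite intensities.
#' @param sigma_mm positive scale in mm. A warning is issued when
#'   `sigma_mm < max(spacing)/2` (kernel under-resolved).
#' @param mode boundary mode, `"symmetric"` (default) or `"periodic"`.
#' @return A [voxel_volume()] on the same grid.
#' @export
log_filter <- function(volume, sigma_mm, mode = "symmetric") {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("sigma_mm must be a single positive number")
  sp <- volume$spacing
  if (sigma_mm < max(sp) / 2)
    warning("LoG sigma ", sigma_mm, " mm is below half the largest voxel spacing")
  a <- volume$intensities
  if (any(!is.finite(a))) stop("volume contains non-finite intensities")
  g <- lapply(1:3, function(ax) gaussian_taps(sigma_mm, sp[ax], radius_sigmas = 6))
  g2 <- lapply(1:3, function(ax) gaussian_d2_taps(sigma_mm, sp[ax], radius_sigmas = 6))
  out <- array(0, dim = dim(a))
  for (dax in 1:3) {
    term <- a
    for (ax in 1:3) {
      k <- if (ax == dax) g2[[ax]] else g[[ax]]
      term <- convolve_axis(term, k, ax, mode = mode)
    }
    out <- out + term
  }
  voxel_volume(out * prod(sp), sp, volume$origin)
}

#' Stationary wavelet sub-bands
#'
#' Single-level undecimated separable 3D wavelet transform: every sub-band
#' has the same shape as the input, so the original tumor mask is reusable
#' unchanged. Sub-band letters are ordered by axis: `"HLH"` applies the
#' high-pass along x, low-pass along y, high-pass along z.
#'
#' @param volume a [voxel_volume()].
#' @param kernel wavelet kernel name (see [filter_bank_config()]).
#' @param subbands sub-band names to return (default all 8).
#' @param mode boundary mode, `"symmetric"` or `"periodic"`.
#' @return Named list of [voxel_volume()]s, names `wv.<subband>`.
#' @export
wavelet_subbands <- function(volume, kernel = "coif1",
                             subbands = c("LLL", "LLH", "LHL", "LHH",
                                          "HLL", "HLH", "HHL", "HHH"),
                             mode = "symmetric") {
  kf <- wavelet_kernels(kernel)
  a <- volume$intensities
  if (any(!is.finite(a))) stop("volume contains non-finite intensities")
  needed <- unique(subbands)
  # filter axis-by-axis, sharing partial results across sub-bands
  partial <- list(root = a)
  for (ax in 1:3) {
    nxt <- list()
    pre <- unique(substr(needed, 1L, ax))
    for (p in pre) {
      head <- paste0("root", substr(p, 1L, ax - 1L))
      k <- if (substr(p, ax, ax) == "L") kf$lo else kf$hi
      nxt[[paste0("root", p)]] <- convolve_axis(partial[[head]], k, ax,
                                                mode = mode)
    }
    partial <- nxt
  }
  out <- lapply(needed, function(sb)
    voxel_volume(partial[[paste0("root", sb)]], volume$spacing, volume$origin))
  names(out) <- paste0("wv.", needed)
  out[paste0("wv.", subbands)]
}

#' Apply the configured filter bank
#'
#' @param volume a [voxel_volume()].
#' @param config a [filter_bank_config()].
#' @return Named list of [voxel_volume()]s: `log.sigma<s>` for each LoG scale
#'   then `wv.<subband>` for each sub-band, all on the original grid.
#' @export
apply_filter_bank <- function(volume, config = filter_bank_config()) {
  stopifnot(inherits(config, "filter_bank_config"))
  out <- list()
  for (s in config$log_sigmas_mm)
    out[[paste0("log.sigma", format(s, trim = TRUE))]] <- log_filter(volume, s)
  if (length(config$subbands))
    out <- c(out, wavelet_subbands(volume, config$wavelet, config$subbands))
  out
}
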