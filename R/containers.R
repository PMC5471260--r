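#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D grid of CT intensities in Hounsfield units (HU)
#' together with its physical geometry. Arrays are indexed `[x, y, z]`
#' (first array dimension = x axis), voxel centres are the physical sample
#' points, and `origin` is the physical coordinate of voxel `[1, 1, 1]`.
#' This axis convention is used everywhere in the package.
#'
#' @param intensities 3D numeric array of intensities (HU).
#' @param spacing numeric length-3, voxel spacing in mm along (x, y, z);
#'   all strictly positive and finite. Anisotropic spacing (e.g. 1.5 mm
#'   slices) is supported.
#' @param origin numeric length-3, physical coordinate (mm) of voxel
#'   `[1, 1, 1]`. Default `c(0, 0, 0)`.
#' @return An object of class `voxel_volume` with fields `intensities`,
#'   `spacing`, `origin`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array (got ",
         paste(dim(intensities), collapse = "x"), "); expected 3 dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be three finite values (mm)")
  structure(list(intensities = intensities, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  rng <- range(x$intensities, finite = TRUE)
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$intensities)

#' Construct a region (tumor) mask
#'
#' A binary mask aligned voxel-for-voxel with a companion [voxel_volume()].
#' Any nonzero voxel is foreground, so 0/1 and 0/255 encodings are both
#' accepted.
#'
#' @param voxels 3D array; coerced to logical by `voxels != 0`.
#' @param spacing,origin as in [voxel_volume()].
#' @return An object of class `region_mask` with logical field `voxels`.
#' @export
region_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask must be a 3D array; expected 3 dimensions")
  v <- array(voxels != 0, dim = dim(voxels))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  structure(list(voxels = v, spacing = spacing, origin = as.numeric(origin)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<region_mask> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @export
dim.region_mask <- function(x) dim(x$voxels)

# Internal: check volume/mask alignment (shape exactly, spacing to tol mm).
check_aligned <- function(volume, mask, tol = 1e-4) {
  if (!identical(dim(volume$intensities), dim(mask$voxels)))
    stop("mask shape (", paste(dim(mask$voxels), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$intensities), collapse = "x"), ")")
  if (any(abs(volume$spacing - mask$spacing) > tol))
    stop("mask spacing differs from volume spacing by more than ", tol, " mm")
  invisible(TRUE)
}

# Internal: foreground voxel check used by every extraction entry point.
check_nonempty_mask <- function(mask, what = "mask") {
  if (!any(mask$voxels)) stop("empty mask: ", what, " has no foreground voxel")
  invisible(TRUE)
}
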