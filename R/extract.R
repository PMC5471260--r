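#' Extract the radiomic feature vector of one subject
#'
#' On the original image: 13 shape + 12 statistics + 17 GLCM + 1 GLSZM +
#' 5 RLGL = 48 features. On every filtered image produced by the filter
#' bank: 12 statistics + 23 textural features (shape is excluded -- the
#' geometry does not depend on the filter), with the gray-level
#' discretization recomputed per image. Feature names are
#' `<filter>.<family>.<feature>` with filter `orig`, `log.sigma<s>` or
#' `wv.<subband>`; the default bank yields `48 + 13 * 35 = 503` features.
#'
#' @param volume a [voxel_volume()].
#' @param mask an aligned [region_mask()].
#' @param filter_config a [filter_bank_config()], or `NULL` for original-image
#'   features only.
#' @param bin_width_hu discretization bin width (default 25 HU).
#' @param glcm_distance GLCM voxel distance (default 1).
#' @param connectivity GLSZM zone connectivity, 26 (default) or 6.
#' @return Named numeric vector; NaN marks declared-undefined values.
#' @export
extract_features <- function(volume, mask, filter_config = NULL,
                             bin_width_hu = 25, glcm_distance = 1L,
                             connectivity = 26L) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  one_image <- function(img) {
    disc <- discretize(img, mask, bin_width_hu)
    c(stats = suppressMessages(intensity_statistics(img, mask, bin_width_hu)),
      glcm = glcm_features(disc, glcm_distance),
      glszm.size_zone_variability =
        glszm_size_zone_variability(disc, connectivity),
      rlgl = rlgl_features(disc))
  }
  sf <- shape_features(mask)
  names(sf) <- paste0("shape.", names(sf))
  out <- c(sf, one_image(volume))
  names(out) <- paste0("orig.", names(out))
  if (!is.null(filter_config)) {
    for (fn in names(filtered <- apply_filter_bank(volume, filter_config))) {
      fv <- one_image(filtered[[fn]])
      names(fv) <- paste0(fn, ".", names(fv))
      out <- c(out, fv)
    }
  }
  out
}

#' Extract a feature table for a list of subjects
#'
#' @param volumes named list of [voxel_volume()]s (names = subject ids).
#' @param masks named list of aligned [region_mask()]s, same names.
#' @param ... passed to [extract_features()].
#' @return data.frame: `subject_id` + one numeric column per feature, columns
#'   identical across subjects.
#' @export
extract_feature_table <- function(volumes, masks, ...) {
  ids <- names(volumes)
  if (is.null(ids) || !identical(sort(ids), sort(names(masks))))
    stop("volumes and masks must be named lists with matching subject ids")
  rows <- lapply(ids, function(id)
    extract_features(volumes[[id]], masks[[id]], ...))
  cols <- names(rows[[1]])
  for (r in rows) if (!identical(names(r), cols))
    stop("inconsistent feature columns across subjects")
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(subject_id = ids, out, stringsAsFactors = FALSE)
}
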