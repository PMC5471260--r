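#' Read a 3D volume from NIfTI or NRRD
#'
#' Reads a CT-like volume (intensities unmodified, spacing taken from the
#' header) into a [voxel_volume()]. NIfTI (`.nii`, `.nii.gz`) is read through
#' the RNifti package; NRRD (`.nrrd`) through a minimal built-in reader
#' supporting 3D raw/gzip little-endian files as written by [write_volume()].
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header in ", path,
                                           ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("image ", path, " has ", length(d), " dimensions; expected 3 dimensions")
  pd <- RNifti::pixdim(img)
  voxel_volume(array(as.numeric(img), dim = d), spacing = pd[1:3],
               origin = nifti_origin(img))
}

nifti_origin <- function(img) {
  o <- tryCatch(unname(RNifti::origin(img)), error = function(e) c(1, 1, 1))
  # RNifti origin is the (1-based) voxel index of the physical origin;
  # convert to the physical coordinate of voxel [1,1,1].
  -(o - 1) * RNifti::pixdim(img)[1:3]
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param volume a [voxel_volume()] (or [region_mask()], written as 0/1).
#' @param path output path; format chosen from the extension
#'   (`.nii`/`.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "region_mask"))
    volume <- voxel_volume(array(as.numeric(volume$voxels), dim(volume$voxels)),
                           volume$spacing, volume$origin)
  if (!inherits(volume, "voxel_volume")) stop("volume must be a voxel_volume")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(write_nrrd(volume, path))
  a <- volume$intensities
  attr(a, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
  invisible(path)
}

#' Read a tumor mask aligned to a companion volume
#'
#' Any nonzero voxel is foreground. The mask must match the companion's grid
#' shape exactly and its spacing to within 1e-4 mm.
#'
#' @param path mask file (NIfTI or NRRD).
#' @param companion the [voxel_volume()] the mask segments.
#' @param subject optional subject label used in error messages.
#' @return A [region_mask()].
#' @export
read_mask <- function(path, companion, subject = basename(path)) {
  v <- read_volume(path)
  if (!identical(dim(v$intensities), dim(companion$intensities)))
    stop("mask shape (", paste(dim(v$intensities), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(companion$intensities), collapse = "x"), ") for ", subject)
  if (any(abs(v$spacing - companion$spacing) > 1e-4))
    stop("mask spacing misaligned with volume (> 1e-4 mm) for ", subject)
  m <- region_mask(v$intensities, companion$spacing, companion$origin)
  if (!any(m$voxels)) stop("empty mask for ", subject)
  m
}

# ---- minimal NRRD0004 support (3D, raw or gzip, little-endian) --------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unreadable header (no data section) in ", path)
    if (line == "") break
    header <- c(header, line)
  }
  if (!grepl("^NRRD", header[1])) stop("unreadable header: not NRRD in ", path)
  fields <- header[grepl("^[^#].*:", header)]
  key <- tolower(sub(":.*", "", fields))
  val <- trimws(sub("^[^:]*:=?", "", fields))
  getf <- function(k) if (k %in% key) val[match(k, key)] else NA_character_
  ndim <- as.integer(getf("dimension"))
  if (is.na(ndim) || ndim != 3L)
    stop("image ", path, " has ", ndim, " dimensions; expected 3 dimensions")
  sizes <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
  type <- getf("type")
  enc <- getf("encoding")
  spacing <- rep(1, 3)
  sd <- getf("space directions")
  if (!is.na(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    m <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  } else if (!is.na(getf("spacings"))) {
    spacing <- as.numeric(strsplit(getf("spacings"), "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  so <- getf("space origin")
  if (!is.na(so)) origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
  n <- prod(sizes)
  rtype <- switch(type,
                  "double" = list(what = "double", size = 8L),
                  "float" = list(what = "double", size = 4L),
                  "int" = , "int32" = list(what = "integer", size = 4L),
                  "short" = , "int16" = list(what = "integer", size = 2L),
                  "uchar" = , "uint8" = list(what = "integer", size = 1L),
                  stop("unsupported NRRD type '", type, "' in ", path))
  raw_rest <- readBin(con, what = "raw", n = file.size(path))
  if (identical(enc, "gzip") || identical(enc, "gz"))
    raw_rest <- memDecompress(raw_rest, type = "gzip")
  else if (!identical(enc, "raw"))
    stop("unsupported NRRD encoding '", enc, "' in ", path)
  vals <- readBin(raw_rest, what = rtype$what, n = n, size = rtype$size,
                  endian = "little", signed = rtype$size > 1L)
  voxel_volume(array(as.numeric(vals), dim = sizes), spacing, origin)
}

write_nrrd <- function(volume, path) {
  d <- dim(volume$intensities)
  sp <- volume$spacing
  hdr <- c("NRRD0004",
           "# written by radsem",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "encoding: raw",
           "endian: little",
           "space dimension: 3",
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   sp[1], sp[2], sp[3]),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$intensities), con, size = 8L, endian = "little")
  invisible(path)
}

# ---- semantic score tables --------------------------------------------------

SEMANTIC_BINARY <- c("cavitation", "air_bronchogram", "calcification")
SEMANTIC_CATEGORICAL <- c("texture", "border_definition", "contour",
                          "lobulation", "spiculation", "concavity")

#' Allowed score ranges of the nine semantic features
#'
#' Binary features (cavitation, air bronchogram, calcification) are scored
#' 0 = absence / 1 = presence. Categorical features are ordinal: texture
#' (1 = non-solid/GGO, 2 = part-solid, 3 = solid), border definition (1 =
#' well defined ... 3 = poorly defined), contour (1 = round ... 4 =
#' irregular), lobulation (1 = none ... 4 = severe), spiculation (1 = none,
#' 2 = fine, 3 = coarse), concavity (1 = none, 2 = slight, 3 = deep).
#'
#' @return Named list mapping each semantic feature to its legal integer scores.
#' @export
semantic_score_ranges <- function() {
  list(cavitation = 0:1, air_bronchogram = 0:1, calcification = 0:1,
       texture = 1:3, border_definition = 1:3, contour = 1:4,
       lobulation = 1:4, spiculation = 1:3, concavity = 1:3)
}

#' Validate a table of semantic scores
#'
#' Checks the nine-score schema: all columns present, subject ids unique, no
#' missing values, every score an integer inside its legal range.
#'
#' @param df data.frame with `subject_id` plus the nine semantic columns.
#' @return The validated data.frame (scores as integers), invisibly classed
#'   `cohort_table`.
#' @export
validate_semantic_scores <- function(df) {
  ranges <- semantic_score_ranges()
  need <- c("subject_id", names(ranges))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("semantic table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  for (col in names(ranges)) {
    x <- df[[col]]
    if (anyNA(x)) stop("missing value in column '", col, "' for subject ",
                       df$subject_id[which(is.na(x))[1]])
    bad <- !is.finite(x) | x != as.integer(x) | !(x %in% ranges[[col]])
    if (any(bad)) {
      i <- which(bad)[1]
      stop("subject ", df$subject_id[i], ": score ", x[i], " out of range for '",
           col, "' (allowed: ", paste(range(ranges[[col]]), collapse = ".."), ")")
    }
    df[[col]] <- as.integer(x)
  }
  df <- df[, need]
  class(df) <- c("cohort_table", "data.frame")
  invisible(df)
}

#' Read semantic scores from CSV
#'
#' @param path CSV with a header: `subject_id` plus the nine semantic columns
#'   (see [semantic_score_ranges()]).
#' @return A validated `cohort_table` data.frame.
#' @export
read_semantic_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- validate_semantic_scores(df)
  attr(out, "validated") <- TRUE
  out
}

#' Write semantic scores to CSV
#' @param cohort a validated semantic score data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_semantic_scores <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

# ---- feature tables ---------------------------------------------------------

#' Write a radiomic feature table to CSV
#'
#' One row per subject; columns are `subject_id` then feature columns named
#' `<filter>.<family>.<feature>` (filter one of `orig`, `log.sigma<s>`,
#' `wv.<subband>`) in their deterministic extraction order. Declared-undefined
#' feature values (`NaN`) are serialized as empty cells and reported via a
#' message.
#'
#' @param table data.frame with `subject_id` + numeric feature columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0L) stop("feature table is empty")
  nan_cols <- names(table)[vapply(table, function(x) is.numeric(x) && any(is.nan(x)),
                                  logical(1))]
  if (length(nan_cols))
    message("feature table: undefined (NaN) values in ",
            length(nan_cols), " column(s), written as empty cells")
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a radiomic feature table from CSV
#' @param path CSV written by [write_feature_table()].
#' @return data.frame with `subject_id` character and numeric feature columns;
#'   empty cells become `NaN` (declared-undefined).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$subject_id <- as.character(df$subject_id)
  for (col in setdiff(names(df), "subject_id")) {
    x <- as.numeric(df[[col]])
    x[is.na(x)] <- NaN
    df[[col]] <- x
  }
  df
}
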