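#' Default semantic score marginals
#'
#' Per-feature score probabilities used by [sample_semantic_scores()].
#' Defaults are the observed proportions in a 258-patient lung
#' adenocarcinoma cohort: cavitation 41/59%, air bronchogram 45/55%,
#' calcification 89/11%, texture 2/26/71%, border definition 5/69/26%,
#' contour 7/10/64/19%, lobulation 4/45/40/12%, spiculation 24/33/43%,
#' concavity 4/61/36% (scores in increasing order; binary order 0, 1).
#'
#' @return Named list of probability vectors, one per semantic feature,
#'   each named by score and summing to 1.
#' @export
semantic_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    cavitation = stats::setNames(norm(c(106, 152)), 0:1),
    air_bronchogram = stats::setNames(norm(c(116, 142)), 0:1),
    calcification = stats::setNames(norm(c(229, 29)), 0:1),
    texture = stats::setNames(norm(c(6, 68, 184)), 1:3),
    border_definition = stats::setNames(norm(c(13, 178, 67)), 1:3),
    contour = stats::setNames(norm(c(17, 26, 166, 49)), 1:4),
    lobulation = stats::setNames(norm(c(10, 115, 102, 31)), 1:4),
    spiculation = stats::setNames(norm(c(63, 85, 110)), 1:3),
    concavity = stats::setNames(norm(c(9, 156, 93)), 1:3))
}

#' Sample a cohort of semantic score records
#'
#' Draws `n` independent records, one score per semantic feature, from
#' per-feature marginal probability tables (independent across features).
#'
#' @param n number of subjects (>= 1).
#' @param marginals named list as returned by [semantic_marginals()]; each
#'   element must be a probability vector named by scores inside the legal
#'   range of its feature and summing to 1.
#' @param seed integer RNG seed.
#' @return A validated `cohort_table` with subject ids `S001, S002, ...`.
#' @export
sample_semantic_scores <- function(n, marginals = semantic_marginals(),
                                   seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  ranges <- semantic_score_ranges()
  miss <- setdiff(names(ranges), names(marginals))
  if (length(miss)) stop("marginals missing for: ", paste(miss, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)))
  for (col in names(ranges)) {
    p <- marginals[[col]]
    sc <- as.integer(names(p))
    if (anyNA(sc) || !all(sc %in% ranges[[col]]))
      stop("marginal for '", col, "' has mass outside the legal score range")
    if (abs(sum(p) - 1) > 1e-8)
      stop("marginal for '", col, "' does not sum to 1")
    df[[col]] <- sample(sc, n, replace = TRUE, prob = p)
  }
  validate_semantic_scores(df)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Map semantic scores to phantom generator knobs
#'
#' Deterministic, frozen score-to-knob mapping. Surface perturbation
#' amplitudes grow linearly with their driving score: lobulation adds a
#' low-angular-frequency undulation (`0.14 * (score - 1)`), spiculation a
#' high-frequency spike field (`0.06 * (score - 1)`), contour an
#' intermediate-frequency irregularity plus axis anisotropy, and concavity
#' subtracts `score - 1` spherical bites. Cavitation additionally
#' contributes a small high-frequency roughness term (+0.08), emulating the
#' clinical covariance of cavitating tumors with irregular shape. Border
#' definition sets the Gaussian edge blur (0.5/1.3/2.1 mm for scores
#' 1/2/3); texture selects the interior fill (non-solid/GGO hazy -550 HU
#' with vessel-like strands, part-solid -350 HU with a solid core, solid
#' +40 HU).
#'
#' @param semantic one-row data.frame (or coercible list) of the nine scores.
#' @param base_radius_mm tumor base radius in mm (default 13).
#' @param noise_sd_hu additive Gaussian noise SD in HU (default 30).
#' @param seed integer seed driving the subject's random geometry.
#' @return A `phenotype_spec` list of knobs (ground truth for recovery tests).
#' @export
phenotype_spec <- function(semantic, base_radius_mm = 13, noise_sd_hu = 30,
                           seed = 1L) {
  s <- as.list(semantic)
  ranges <- semantic_score_ranges()
  for (col in names(ranges))
    if (is.null(s[[col]]) || !(s[[col]] %in% ranges[[col]]))
      stop("invalid or missing semantic score '", col, "'")
  axis_ratio <- c(1, 1.3, 1.3, 1.45)[s$contour]
  structure(list(
    semantic = s,
    base_radius_mm = base_radius_mm,
    lobulation_amplitude = 0.14 * (s$lobulation - 1),
    spiculation_amplitude = 0.06 * (s$spiculation - 1) + 0.08 * s$cavitation,
    contour_amplitude = c(0, 0, 0.06, 0.12)[s$contour],
    axis_ratio = axis_ratio,
    concavity_bites = s$concavity - 1L,
    bite_radius_frac = 0.15 + 0.15 * (s$concavity - 1),
    border_blur_sigma_mm = 0.5 + 0.8 * (s$border_definition - 1),
    base_hu = c(-550, -350, 40)[s$texture],
    noise_sd_hu = noise_sd_hu,
    cavity_fraction = if (s$cavitation == 1) 0.5 else 0,
    calcification_count = if (s$calcification == 1) 2L else 0L,
    bronchogram_tube_radius_mm = if (s$air_bronchogram == 1) 1.2 else 0,
    seed = as.integer(seed)), class = "phenotype_spec")
}

# smooth random directional cosine field on the unit sphere
.angular_field <- function(ux, uy, uz, n_bumps, freq_range) {
  if (n_bumps == 0L) return(0)
  out <- 0
  for (b in seq_len(n_bumps)) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    f <- stats::runif(1, freq_range[1], freq_range[2])
    ph <- stats::runif(1, 0, 2 * pi)
    out <- out + cos(f * (ux * d[1] + uy * d[2] + uz * d[3]) + ph)
  }
  out / n_bumps
}

#' Build one CT tumor phantom
#'
#' Renders a star-convex tumor with radial surface
#' `r(u) = R * (1 + lobulation + contour-irregularity + spiculation terms)`
#' minus concavity bites, inside a lung-like background (-800 HU). The
#' interior fill follows the texture score; cavitation carves a central air
#' cavity (-950 HU), air bronchogram an air tube, calcification stamps
#' small (+600 HU, <= 3 mm) spots. The volume is then edge-blurred with the
#' border-definition sigma and Gaussian noise is added. The returned mask
#' is the rendered tumor support before blurring. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [phenotype_spec()].
#' @param grid_shape integer triple, default `c(64, 64, 64)`.
#' @param spacing mm triple, default 1 mm isotropic.
#' @return A `phantom_subject` list: `volume`, `mask`, `semantic`, `truth`.
#' @export
build_phantom <- function(spec, grid_shape = c(64, 64, 64),
                          spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "phenotype_spec"))
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  R <- spec$base_radius_mm
  amp <- spec$lobulation_amplitude + spec$contour_amplitude +
    spec$spiculation_amplitude
  half_extent <- (grid_shape - 1) / 2 * spacing
  r_need <- R * (1 + amp) * spec$axis_ratio^(2 / 3)
  fit <- half_extent - 2 * spacing
  if (any(r_need > fit)) {
    need <- ceiling(2 * (r_need / spacing + 3))
    stop("tumor (radius ", round(r_need, 1), " mm) does not fit grid; ",
         "minimum grid shape about ", paste(need, collapse = "x"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  # physical coordinates relative to the grid centre, then a random rotation
  cx <- (seq_len(grid_shape[1]) - 1 - (grid_shape[1] - 1) / 2) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 1 - (grid_shape[2] - 1) / 2) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 1 - (grid_shape[3] - 1) / 2) * spacing[3]
  X <- array(cx, grid_shape)
  Y <- array(rep(cy, each = grid_shape[1]), grid_shape)
  Z <- array(rep(cz, each = grid_shape[1] * grid_shape[2]), grid_shape)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  RX <- Q[1, 1] * X + Q[1, 2] * Y + Q[1, 3] * Z
  RY <- Q[2, 1] * X + Q[2, 2] * Y + Q[2, 3] * Z
  RZ <- Q[3, 1] * X + Q[3, 2] * Y + Q[3, 3] * Z
  # volume-preserving axis scaling realises the contour anisotropy:
  # physical semi-axes (R*ratio^(2/3), R*ratio^(-1/3), R*ratio^(-1/3))
  s <- c(spec$axis_ratio^(2 / 3), spec$axis_ratio^(-1 / 3),
         spec$axis_ratio^(-1 / 3))
  SX <- RX / s[1]; SY <- RY / s[2]; SZ <- RZ / s[3]
  m <- sqrt(SX^2 + SY^2 + SZ^2)
  m0 <- pmax(m, 1e-9)
  ux <- SX / m0; uy <- SY / m0; uz <- SZ / m0

  lob <- .angular_field(ux, uy, uz, 4L, c(3, 6))
  irr <- .angular_field(ux, uy, uz, 4L, c(4, 7))
  spic <- .angular_field(ux, uy, uz, 6L, c(8, 14))
  r_u <- R * (1 + spec$lobulation_amplitude * lob +
                spec$contour_amplitude * irr +
                spec$spiculation_amplitude * spic)
  support <- m <= r_u
  # concavity: subtract spherical bites centred on the surface
  for (b in seq_len(spec$concavity_bites)) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    cb <- d * R  # bite centre at the base-radius surface
    br <- spec$bite_radius_frac * R
    support <- support &
      ((SX - cb[1])^2 + (SY - cb[2])^2 + (SZ - cb[3])^2 > br^2)
  }
  if (!any(support)) stop("degenerate phantom: empty tumor support")

  vol <- array(-800, grid_shape)  # lung parenchyma background
  vol[support] <- spec$base_hu
  tex <- spec$semantic$texture
  if (tex <= 2L) {
    # sub-solid interiors keep vessel-like bright strands and a hazy,
    # mottled attenuation pattern (ground-glass lesions do not obscure the
    # underlying structure, so they are locally heterogeneous)
    for (k in 1:2) {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      o <- stats::rnorm(3, sd = 0.25 * R)
      px <- SX - o[1]; py <- SY - o[2]; pz <- SZ - o[3]
      t <- px * d[1] + py * d[2] + pz * d[3]
      dist2 <- px^2 + py^2 + pz^2 - t^2
      vol[support & dist2 <= 0.8^2] <- 30
    }
    if (tex == 2L) vol[support & m <= 0.55 * R] <- 40  # solid core
  }
  if (spec$cavity_fraction > 0) {
    o <- stats::rnorm(3, sd = 0.1 * R)
    cav <- support &
      ((SX - o[1])^2 + (SY - o[2])^2 + (SZ - o[3])^2 <=
         (spec$cavity_fraction * R)^2)
    vol[cav] <- -950
    # cavitation arises from patchy central necrosis: satellite necrotic
    # pockets at intermediate attenuation add genuine zone-size diversity
    pk_hu <- spec$base_hu + c(-450, 350, -300, 250, -380, 300, -200, 150)
    for (k in 1:8) {
      o <- stats::rnorm(3, sd = 0.5 * R)
      pk <- support &
        ((SX - o[1])^2 + (SY - o[2])^2 + (SZ - o[3])^2 <= (0.25 * R)^2)
      vol[pk] <- pk_hu[k]
    }
  }
  if (spec$bronchogram_tube_radius_mm > 0) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    t <- SX * d[1] + SY * d[2] + SZ * d[3]
    dist2 <- SX^2 + SY^2 + SZ^2 - t^2
    vol[support & dist2 <= spec$bronchogram_tube_radius_mm^2] <- -950
  }
  if (spec$calcification_count > 0) {
    for (k in seq_len(spec$calcification_count)) {
      o <- stats::rnorm(3, sd = 0.35 * R)
      vol[support & ((SX - o[1])^2 + (SY - o[2])^2 + (SZ - o[3])^2 <= 1.2^2)] <- 600
    }
  }
  vol <- gaussian_smooth(vol, spec$border_blur_sigma_mm, spacing)
  vol <- vol + array(stats::rnorm(prod(grid_shape), sd = spec$noise_sd_hu),
                     grid_shape)
  if (tex <= 2L) {
    # sub-solid lesions do not obscure the lung architecture: voxel-scale
    # speckle makes their interiors locally heterogeneous
    sd_speckle <- c(70, 40)[tex]
    vol[support] <- vol[support] +
      stats::rnorm(sum(support), sd = sd_speckle)
  }

  structure(list(volume = voxel_volume(vol, spacing),
                 mask = region_mask(support, spacing),
                 semantic = spec$semantic,
                 truth = spec),
            class = "phantom_subject")
}

#' Generate and write a phantom cohort
#'
#' Samples semantic scores, renders one phantom per subject and writes the
#' cohort to disk: `<id>_volume.nii.gz`, `<id>_mask.nii.gz` per subject,
#' `semantic_scores.csv`, and `ground_truth.json` with every subject's
#' generator knobs. Per-subject seeds are derived from the master seed by
#' the counter scheme `(seed * 1009 + subject_index) mod (2^31 - 1)`.
#'
#' @param n number of subjects (>= 1).
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing and return phantoms in memory.
#' @param seed master integer seed.
#' @param marginals semantic score marginals (default [semantic_marginals()]).
#' @param grid_shape,spacing phantom grid geometry.
#' @param base_radius_mm,noise_sd_hu generator knobs per [phenotype_spec()].
#' @return Invisibly, a list: `cohort` (score table), `phantoms` (list of
#'   `phantom_subject`, only when `out_dir` is NULL), `files`.
#' @export
generate_cohort <- function(n, out_dir = NULL, seed = 1L,
                            marginals = semantic_marginals(),
                            grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                            base_radius_mm = 13, noise_sd_hu = 30) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cohort <- sample_semantic_scores(n, marginals, seed)
  subject_seed <- function(i) (as.numeric(seed) * 1009 + i) %% 2147483647
  phantoms <- NULL
  files <- character(0)
  truth <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  keep <- is.null(out_dir)
  if (keep) phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phenotype_spec(cohort[i, ], base_radius_mm = base_radius_mm,
                           noise_sd_hu = noise_sd_hu, seed = subject_seed(i))
    ph <- build_phantom(spec, grid_shape, spacing)
    id <- cohort$subject_id[i]
    truth[[id]] <- spec[setdiff(names(spec), "semantic")]
    if (keep) {
      phantoms[[i]] <- ph
    } else {
      vf <- file.path(out_dir, paste0(id, "_volume.nii.gz"))
      mf <- file.path(out_dir, paste0(id, "_mask.nii.gz"))
      write_volume(ph$volume, vf)
      write_volume(ph$mask, mf)
      files <- c(files, vf, mf)
    }
  }
  if (keep) names(phantoms) <- cohort$subject_id
  if (!is.null(out_dir)) {
    sf <- file.path(out_dir, "semantic_scores.csv")
    write_semantic_scores(cohort, sf)
    tf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
    files <- c(files, sf, tf)
  }
  invisible(list(cohort = cohort, phantoms = phantoms, files = files))
}
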