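#' Pipeline configuration
#'
#' Builds, validates and completes the configuration for the four-stage
#' pipeline (generate, extract, select, associate). Unknown keys anywhere in
#' the structure are an error, so typos cannot silently fall back to
#' defaults. Can be read from a YAML file with [read_pipeline_config()].
#'
#' @param config named list overriding defaults; blocks `cohort` (n_subjects, seed,
#'   grid_shape, spacing, base_radius_mm, noise_sd_hu, marginals), `filters`
#'   (log_sigmas_mm, wavelet, subbands, enabled), `features` (bin_width_hu,
#'   glcm_distance, connectivity), `selection` (rho_threshold), `association`
#'   (alpha, min_n).
#' @return A completed `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    cohort = list(n_subjects = 20L, seed = 1L, grid_shape = c(64L, 64L, 64L),
                  spacing = c(1, 1, 1), base_radius_mm = 13,
                  noise_sd_hu = 30, marginals = semantic_marginals()),
    filters = list(enabled = TRUE, log_sigmas_mm = c(1, 2, 3, 4, 5),
                   wavelet = "coif1",
                   subbands = c("LLL", "LLH", "LHL", "LHH",
                                "HLL", "HLH", "HHL", "HHH")),
    features = list(bin_width_hu = 25, glcm_distance = 1L, connectivity = 26L),
    selection = list(rho_threshold = 0.85),
    association = list(alpha = 0.05, min_n = 10L))
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(unknown))
      stop("unknown config key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "))
    defaults[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the blocks documented in [pipeline_config()].
#' @return A completed `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_filter_bank <- function(config) {
  if (!isTRUE(config$filters$enabled)) return(NULL)
  filter_bank_config(config$filters$log_sigmas_mm, config$filters$wavelet,
                     config$filters$subbands)
}

# Run manifest: config hash, seeds, per-file md5 digests, version, timestamp.
write_manifest <- function(out_dir, stage, config, files) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  cfg2 <- unclass(config)
  cfg2$cohort$marginals <- lapply(cfg2$cohort$marginals, unname)
  jsonlite::write_json(cfg2, cfg_file, auto_unbox = TRUE, digits = NA)
  files <- files[file.exists(files)]
  manifest <- list(stage = stage,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$cohort$seed,
                   tool_version =
                     as.character(utils::packageVersion("radsem")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Pipeline stage: generate the synthetic cohort
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing).
#' @return Invisibly, the cohort score table.
#' @export
run_generate <- function(config, out_dir) {
  config <- pipeline_config(unclass(config))
  cdir <- file.path(out_dir, "cohort")
  co <- config$cohort
  res <- generate_cohort(co$n_subjects, out_dir = cdir, seed = co$seed,
                         marginals = co$marginals, grid_shape = co$grid_shape,
                         spacing = co$spacing,
                         base_radius_mm = co$base_radius_mm,
                         noise_sd_hu = co$noise_sd_hu)
  write_manifest(out_dir, "generate", config, res$files)
  invisible(res$cohort)
}

#' Pipeline stage: extract the feature table
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory containing `cohort/` from [run_generate()].
#' @return Invisibly, the feature table (also written to `features.csv`).
#' @export
run_extract <- function(config, out_dir) {
  config <- pipeline_config(unclass(config))
  cdir <- file.path(out_dir, "cohort")
  cohort <- read_semantic_scores(file.path(cdir, "semantic_scores.csv"))
  fb <- config_filter_bank(config)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    vf <- file.path(cdir, paste0(id, "_volume.nii.gz"))
    mf <- file.path(cdir, paste0(id, "_mask.nii.gz"))
    if (!file.exists(vf)) stop("missing volume file for subject ", id)
    if (!file.exists(mf)) stop("missing mask file for subject ", id)
    vol <- read_volume(vf)
    msk <- read_mask(mf, vol, subject = id)
    rows[[i]] <- extract_features(vol, msk, fb,
                                  bin_width_hu = config$features$bin_width_hu,
                                  glcm_distance = config$features$glcm_distance,
                                  connectivity = config$features$connectivity)
    message("extracted ", length(rows[[i]]), " features for ", id)
  }
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab <- cbind(subject_id = cohort$subject_id, tab, stringsAsFactors = FALSE)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(tab, fpath)
  write_manifest(out_dir, "extract", config, fpath)
  invisible(tab)
}

#' Pipeline stage: prune redundant features
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory containing `features.csv`.
#' @return Invisibly, the [prune_redundant()] selection report; writes
#'   `features_pruned.csv`, `selection_report.csv` and `selection_report.json`.
#' @export
run_select <- function(config, out_dir) {
  config <- pipeline_config(unclass(config))
  tab <- read_feature_table(file.path(out_dir, "features.csv"))
  rep <- prune_redundant(spearman_matrix(tab), config$selection$rho_threshold)
  pruned <- tab[, c("subject_id", rep$kept), drop = FALSE]
  pf <- file.path(out_dir, "features_pruned.csv")
  write_feature_table(pruned, pf)
  rcsv <- file.path(out_dir, "selection_report.csv")
  utils::write.csv(rep$dropped, rcsv, row.names = FALSE)
  rjson <- file.path(out_dir, "selection_report.json")
  jsonlite::write_json(list(kept = rep$kept, threshold = rep$threshold,
                            dropped = rep$dropped),
                       rjson, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "select", config, c(pf, rcsv, rjson))
  invisible(rep)
}

#' Pipeline stage: association analysis
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory containing `features_pruned.csv` and the
#'   cohort's `semantic_scores.csv`.
#' @return Invisibly, the [build_report()] association report; writes
#'   `associations.csv` (long format) and `association_summary.csv`.
#' @export
run_associate <- function(config, out_dir) {
  config <- pipeline_config(unclass(config))
  tab <- read_feature_table(file.path(out_dir, "features_pruned.csv"))
  cohort <- read_semantic_scores(file.path(out_dir, "cohort",
                                           "semantic_scores.csv"))
  rep <- build_report(tab, cohort, alpha = config$association$alpha,
                      min_n = config$association$min_n)
  af <- file.path(out_dir, "associations.csv")
  utils::write.csv(as.data.frame(rep), af, row.names = FALSE)
  sf <- file.path(out_dir, "association_summary.csv")
  utils::write.csv(summary(rep), sf, row.names = FALSE)
  write_manifest(out_dir, "associate", config, c(af, sf))
  invisible(rep)
}

#' Run the complete pipeline
#'
#' Chains generate, extract, select and associate into one run directory.
#' With `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a [pipeline_config()] (or plain list of overrides).
#' @param out_dir run directory.
#' @param resume skip stages whose outputs already exist (default FALSE).
#' @return Invisibly, the final association report.
#' @export
run_all <- function(config = pipeline_config(), out_dir, resume = FALSE) {
  config <- pipeline_config(unclass(config))
  have <- function(f) resume && file.exists(file.path(out_dir, f))
  if (!have(file.path("cohort", "semantic_scores.csv")))
    run_generate(config, out_dir)
  if (!have("features.csv")) run_extract(config, out_dir)
  if (!have("features_pruned.csv")) run_select(config, out_dir)
  rep <- run_associate(config, out_dir)
  invisible(rep)
}
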