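# File formats, configuration and the end-to-end connectome pipeline.
# Conventions: NIfTI-1 for volumes (via RNifti), labeled CSV for
# matrices with "NA" as the absent-entry sentinel, CSV manifests
# (subject_id, label, file paths). Voxel/block coordinates written to
# disk are 0-based with half-open intervals; the R API is 1-based.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return Numeric array (3D or 4D) with the NIfTI geometry attributes
#'   preserved; malformed files are rejected by the parser.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  RNifti::readNifti(path)
}

#' Write a NIfTI volume
#'
#' @param vol Numeric array (3D or 4D).
#' @param path Output path.
#' @return `path`, invisibly. Data arrays round-trip bit-identically
#'   (written as float64).
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), file = path)
  invisible(path)
}

#' Read a labeled matrix from CSV
#'
#' First column holds row labels, header holds column labels; the
#' token `NA` marks absent entries (used for untracked FA pairs).
#'
#' @param path CSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_matrix: no data columns in ", path)
  rl <- as.character(df[[1]])
  if (anyDuplicated(rl)) stop("read_matrix: duplicate row labels in ", path)
  cl <- colnames(df)[-1]
  if (anyDuplicated(cl)) stop("read_matrix: duplicate column labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_matrix: non-numeric entries in ", path)
  dimnames(m) <- list(rl, cl)
  m
}

#' Write a labeled matrix to CSV
#'
#' @param m Matrix (row/col names kept; `NA` written as the sentinel).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% paste0("r", seq_len(nrow(m))),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort manifest
#'
#' A manifest row is one subject: `subject_id`, `label`, and one column
#' per stored modality file.
#'
#' @param path Manifest CSV.
#' @param check_exists Verify that all referenced files exist.
#' @return Data frame.
#' @export
read_manifest <- function(path, check_exists = TRUE) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% colnames(mf)))
    stop("read_manifest: manifest needs subject_id and label columns")
  if (anyDuplicated(mf$subject_id))
    stop("read_manifest: duplicate subject ids")
  if (check_exists) {
    base <- dirname(path)
    for (col in setdiff(colnames(mf), c("subject_id", "label"))) {
      p <- file.path(base, mf[[col]])
      missing <- !file.exists(p)
      if (any(missing))
        stop("read_manifest: missing file(s): ",
             paste(mf[[col]][missing], collapse = ", "))
    }
  }
  mf
}

#' Write a cohort to disk
#'
#' Time-series and FA cohorts are written as labeled CSV matrices,
#' volume cohorts as NIfTI pairs; a manifest CSV ties subjects, labels
#' and relative file paths together.
#'
#' @param cohort A `ts_cohort`, `fa_cohort` or `volume_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subs <- cohort$subjects
  rows <- lapply(subs, function(s) {
    row <- list(subject_id = s$id, label = s$label)
    if (!is.null(s$ts)) {
      f <- paste0(s$id, "_ts.csv")
      write_matrix(s$ts, file.path(dir, f)); row$ts <- f
    }
    if (!is.null(s$fa)) {
      f <- paste0(s$id, "_fa.csv")
      write_matrix(s$fa, file.path(dir, f)); row$fa <- f
    }
    for (mod in intersect(c("mri", "pet"), names(s))) {
      f <- paste0(s$id, "_", mod, ".nii.gz")
      write_volume(s[[mod]], file.path(dir, f)); row[[mod]] <- f
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  mf <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.pipeline_defaults <- function() {
  list(seed = 1, out_dir = "nc_run",
       groups = c("AD", "NC"),
       n_per_group = c(AD = 15, NC = 15), n_regions = 52,
       n_timepoints = 140, effect_nodes = c(5, 12, 23, 40),
       effect_size = 1, noise_sd = 0.2, absent_frac = 0.15,
       trim = 5, fc_threshold = 0.3, fa_threshold = 0.2,
       alpha = 0.05, correction = "none")
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys.
#'
#' @param cfg Named list (or path to a YAML file).
#' @return Validated configuration list.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defs <- .pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("validate_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  out <- utils::modifyList(defs, cfg)
  # YAML parses vectors as lists; flatten the vector-valued fields
  for (f in c("n_per_group", "effect_nodes", "groups"))
    out[[f]] <- unlist(out[[f]])
  out
}

#' Run the simulate-connectome-select pipeline
#'
#' Generates a synthetic cohort, trims the initial BOLD volumes, builds
#' per-subject FCN and DTISCN networks, extracts the graph-feature
#' table, and performs Welch t-test selection between the two
#' configured groups. Stage outputs land in the run directory together
#' with a machine-readable log (effective configuration, its MD5 hash,
#' seed, package version), so an identical configuration reproduces
#' identical outputs.
#'
#' @param cfg Configuration list or YAML path (see [validate_config()]).
#' @return Invisibly, a list with the feature table, selection result
#'   and output paths.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  spec <- cohort_spec(n_per_group = cfg$n_per_group,
                      n_regions = cfg$n_regions,
                      n_timepoints = cfg$n_timepoints,
                      effect_nodes = cfg$effect_nodes,
                      effect_size = cfg$effect_size,
                      noise_sd = cfg$noise_sd,
                      absent_frac = cfg$absent_frac, seed = cfg$seed)
  feats <- cohort_features(spec, trim = cfg$trim,
                           fc_threshold = cfg$fc_threshold,
                           fa_threshold = cfg$fa_threshold)
  labels <- feats$labels
  g <- cfg$groups
  sel <- ttest_select(feats$features[labels == g[1], , drop = FALSE],
                      feats$features[labels == g[2], , drop = FALSE],
                      alpha = cfg$alpha,
                      correction = cfg$correction)
  fpath <- file.path(cfg$out_dir, "features.csv")
  utils::write.csv(data.frame(subject_id = feats$ids, label = labels,
                              feats$features, check.names = FALSE),
                   fpath, row.names = FALSE)
  spath <- file.path(cfg$out_dir, "selection.csv")
  utils::write.csv(sel, spath, row.names = FALSE)
  log <- list(config = cfg,
              config_md5 = unname(tools::md5sum(cfg_path)),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("neurocascade")),
              n_selected = sum(sel$selected),
              outputs = c(features = fpath, selection = spath))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = feats$features, labels = labels,
                 selection = sel, paths = log$outputs))
}

#' Graph-feature table for a synthetic cohort
#'
#' Generates matched time-series and FA cohorts from one spec, trims
#' the initial volumes, builds each subject's FCN and DTISCN, and
#' stacks the per-subject feature vectors (degree, efficiency,
#' betweenness per node per network) into a table.
#'
#' @param spec A [cohort_spec()].
#' @param trim Initial BOLD volumes to remove.
#' @param fc_threshold Correlation threshold for the FCN.
#' @param fa_threshold FA threshold for the DTISCN.
#' @return List with `features` (subjects x features matrix), `labels`,
#'   `ids`.
#' @export
cohort_features <- function(spec, trim = 5, fc_threshold = 0.3,
                            fa_threshold = 0.2) {
  tsc <- gen_timeseries_cohort(spec)
  fac <- gen_fa_cohort(spec)
  rows <- lapply(seq_along(tsc$subjects), function(i) {
    ts <- trim_initial_volumes(tsc$subjects[[i]]$ts, trim)
    fcn <- build_fcn(compute_fc(ts), fc_threshold)
    dti <- build_dtiscn(fac$subjects[[i]]$fa, fa_threshold)
    extract_features(list(fcn, dti))
  })
  features <- do.call(rbind, rows)
  list(features = features,
       labels = vapply(tsc$subjects, `[[`, "", "label"),
       ids = vapply(tsc$subjects, `[[`, "", "id"))
}
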