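# Occlusion-based discriminative-region mapping: slide a gray cube over
# the input volume, re-evaluate the trained classifier, and record the
# drop in true-class probability at every cube position.

#' Occlusion specification
#'
#' At the full 100 x 81 x 80 scale the occluder is a 15-voxel gray
#' cube; at the package's 4x-scaled-down default geometry that
#' corresponds to the default 4-voxel cube. The fill value is the mean
#' intensity of the input block (`"block_mean"`), or the mean of the
#' covered cube (`"local_mean"`).
#'
#' @param cube Cube side length in voxels.
#' @param stride Scan stride in voxels (>= 1).
#' @param fill `"block_mean"` (scalar mean of the input block, the
#'   canonical gray-cube rule), `"local_mean"` (mean of the covered
#'   cube), or `"reference"` (voxelwise values from a reference
#'   template, i.e. gray in the model's standardized input space;
#'   appropriate when intensities are not globally normalized).
#' @return An `occlusion_spec`.
#' @export
occlusion_spec <- function(cube = 4, stride = 2,
                           fill = c("block_mean", "local_mean",
                                    "reference")) {
  fill <- match.arg(fill)
  stopifnot(cube >= 1, stride >= 1)
  structure(list(cube = as.integer(cube), stride = as.integer(stride),
                 fill = fill), class = "occlusion_spec")
}

#' Occlusion saliency map for one volume
#'
#' For each cube position (deterministic z-major scan order) the map
#' value is `p_true(original) - p_true(occluded)`. Positive values mark
#' regions whose masking hurts the prediction; negative drops
#' (occlusion raising the probability) are retained. Wherever the fill
#' value equals the underlying intensities the input is unchanged and
#' the map value is exactly zero.
#'
#' @param model A trained `nn_model` taking the flattened volume.
#' @param vol 3D array matching the model input.
#' @param spec An [occlusion_spec()].
#' @param class_idx True-class index (1-based) whose probability is
#'   monitored.
#' @param reference Reference volume for `fill = "reference"`
#'   (typically the training-cohort voxel-mean template).
#' @return A `saliency_map`: list with `values` (array over the scan
#'   grid), `centers` (position-center voxel coordinates, rows match
#'   `values` in z-major order), `p_ref`, `spec`.
#' @export
occlusion_map <- function(model, vol, spec = occlusion_spec(),
                          class_idx = 2, reference = NULL) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  if (any(spec$cube > d))
    stop("occlusion_map: cube larger than the volume block")
  if (spec$fill == "reference") {
    if (is.null(reference) || !identical(dim(reference), d))
      stop("occlusion_map: fill = \"reference\" needs a reference volume ",
           "matching the input shape")
    ref <- as.numeric(reference)
  }
  starts <- lapply(d, function(dd) {
    s <- seq(1L, dd - spec$cube + 1L, by = spec$stride)
    as.integer(s)
  })
  grid_dims <- vapply(starts, length, 1L)
  combos <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]],
                                  z = starts[[3]]))
  x0 <- as.numeric(vol)
  p_ref <- nn_predict(model, matrix(x0, ncol = 1))[class_idx, 1]
  fill_global <- mean(vol)
  n <- nrow(combos)
  X <- matrix(x0, length(x0), n)
  idx_cache <- expand.grid(dx = 0:(spec$cube - 1), dy = 0:(spec$cube - 1),
                           dz = 0:(spec$cube - 1))
  for (i in seq_len(n)) {
    cx <- combos[i, 1] + idx_cache$dx
    cy <- combos[i, 2] + idx_cache$dy
    cz <- combos[i, 3] + idx_cache$dz
    lin <- cx + (cy - 1) * d[1] + (cz - 1) * d[1] * d[2]
    X[lin, i] <- switch(spec$fill,
                        block_mean = fill_global,
                        local_mean = mean(x0[lin]),
                        reference = ref[lin])
  }
  p_occ <- nn_predict(model, X)[class_idx, ]
  values <- array(p_ref - p_occ, grid_dims)
  centers <- combos + (spec$cube - 1) / 2
  colnames(centers) <- c("x", "y", "z")
  structure(list(values = values, centers = centers, p_ref = p_ref,
                 spec = spec, vol_dim = d),
            class = "saliency_map")
}

#' Aggregate occlusion maps across subjects
#'
#' Position-wise mean of maps sharing the same scan geometry, with the
#' top-k positions (largest mean probability drop) reported with their
#' center coordinates. A z-scored variant of the aggregate is included
#' alongside the raw mean.
#'
#' @param maps List of [occlusion_map()] results with identical
#'   geometry.
#' @param top_k Number of ranked positions to report.
#' @return List with `mean_map` (array), `z_map`, `ranked` (data frame
#'   of top-k positions), `n_subjects`.
#' @export
aggregate_maps <- function(maps, top_k = 5) {
  if (length(maps) == 0) stop("aggregate_maps: empty input")
  geo <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(geo, identical, TRUE, geo[[1]])))
    stop("aggregate_maps: maps have mismatched geometry")
  ctr <- lapply(maps, `[[`, "centers")
  if (!all(vapply(ctr, identical, TRUE, ctr[[1]])))
    stop("aggregate_maps: maps have mismatched scan positions")
  stack <- vapply(maps, function(m) as.numeric(m$values),
                  numeric(length(maps[[1]]$values)))
  mu <- rowMeans(stack)
  sdv <- stats::sd(mu)
  z <- if (isTRUE(sdv > 0)) (mu - mean(mu)) / sdv else mu * 0
  ord <- order(mu, decreasing = TRUE)[seq_len(min(top_k, length(mu)))]
  ranked <- data.frame(rank = seq_along(ord),
                       ctr[[1]][ord, , drop = FALSE],
                       drop = mu[ord], row.names = NULL)
  list(mean_map = array(mu, dim(maps[[1]]$values)),
       z_map = array(z, dim(maps[[1]]$values)),
       centers = ctr[[1]], ranked = ranked, n_subjects = length(maps))
}

#' Write a saliency analysis to disk
#'
#' The aggregate (or single-subject) map is written as a NIfTI volume
#' over the scan grid and the ranked positions as a CSV table; CSV
#' coordinates are 0-based voxel centers.
#'
#' @param agg An [aggregate_maps()] result (or a single
#'   [occlusion_map()]).
#' @param dir Output directory.
#' @param name Basename for the two files.
#' @return Invisibly, the two paths.
#' @export
write_saliency <- function(agg, dir, name = "saliency") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(agg, "saliency_map"))
    agg <- aggregate_maps(list(agg))
  nii <- file.path(dir, paste0(name, "_map.nii.gz"))
  write_volume(agg$mean_map, nii)
  csv <- file.path(dir, paste0(name, "_ranked.csv"))
  ranked <- agg$ranked
  ranked[, c("x", "y", "z")] <- ranked[, c("x", "y", "z")] - 1
  utils::write.csv(ranked, csv, row.names = FALSE)
  invisible(c(map = nii, ranked = csv))
}

#' Select the best-performing blocks for saliency analysis
#'
#' Ranks blocks by their per-block validation accuracy (averaged over
#' modalities) and returns the indices of the top `k` blocks, the
#' default choice of analysis targets.
#'
#' @param model A [cascade_fit()] bundle.
#' @param k Number of blocks (default 3).
#' @return Integer block indices.
#' @export
top_blocks <- function(model, k = 3) {
  acc <- Reduce(`+`, model$val_acc) / length(model$val_acc)
  order(acc, decreasing = TRUE)[seq_len(min(k, length(acc)))]
}
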