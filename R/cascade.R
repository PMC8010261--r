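# Cascaded single/multimodal 3D classifier: a grid of overlapping image
# blocks, one local 3D net per (modality, block), per-location 2D fusion
# nets over the modalities' intermediate conv features, and a final
# fully-connected combiner. Training protocol throughout: Xavier init,
# Adadelta, batch 64, shift augmentation of the training split only.

#' Crop and downsample a volume
#'
#' Factor-2 (by default) mean downsampling, tight bounding-box crop of
#' the non-background voxels, then center pad/crop to a target shape.
#'
#' @param vol 3D numeric array.
#' @param target Target shape after cropping (or `NULL` to keep the
#'   tight box).
#' @param factor Integer downsampling factor per axis.
#' @param background Values with absolute value at or below this are
#'   background for the crop.
#' @return 3D array of shape `target` (if given).
#' @export
crop_and_downsample <- function(vol, target = NULL, factor = 2,
                                background = 0) {
  stopifnot(length(dim(vol)) == 3)
  f <- rep_len(as.integer(factor), 3)
  d <- dim(vol)
  if (any(f > 1)) {
    d2 <- d %/% f
    if (any(d2 < 1)) stop("crop_and_downsample: factor exceeds volume size")
    v <- vol[seq_len(d2[1] * f[1]), seq_len(d2[2] * f[2]),
             seq_len(d2[3] * f[3]), drop = FALSE]
    dim(v) <- c(f[1], d2[1], f[2], d2[2], f[3], d2[3])
    vol <- apply(v, c(2, 4, 6), mean)
  }
  keep <- which(abs(vol) > background, arr.ind = TRUE)
  if (nrow(keep) == 0) stop("crop_and_downsample: empty volume")
  lo <- apply(keep, 2, min); hi <- apply(keep, 2, max)
  vol <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (is.null(target)) return(vol)
  .pad_or_crop(vol, target)
}

.pad_or_crop <- function(vol, target) {
  d <- dim(vol)
  out <- array(0, target)
  n <- pmin(d, target)
  src0 <- (d - n) %/% 2; dst0 <- (target - n) %/% 2
  out[dst0[1] + seq_len(n[1]), dst0[2] + seq_len(n[2]),
      dst0[3] + seq_len(n[3])] <-
    vol[src0[1] + seq_len(n[1]), src0[2] + seq_len(n[2]),
        src0[3] + seq_len(n[3])]
  out
}

#' Block grid over a volume
#'
#' Divides a volume into a `gx x gy x gz` grid of equally spaced,
#' overlapping blocks (default 3 x 3 x 3 = 27 blocks with ~50%
#' overlap). Block starts are spread so the union of blocks covers the
#' volume.
#'
#' @param vol_shape 3D volume shape.
#' @param grid Blocks per axis.
#' @param overlap Fractional overlap between adjacent blocks.
#' @return A `block_grid`: list with `grid`, `size`, `starts` (list per
#'   axis, 1-based), `n_blocks`.
#' @export
block_grid <- function(vol_shape, grid = c(3, 3, 3), overlap = 0.5) {
  stopifnot(length(vol_shape) == 3, length(grid) == 3, all(grid >= 1))
  if (any(grid > vol_shape)) stop("block_grid: grid larger than volume")
  size <- ifelse(grid == 1, vol_shape,
                 pmin(vol_shape, ceiling(vol_shape / (1 + (grid - 1) * (1 - overlap)))))
  starts <- lapply(1:3, function(a) {
    if (grid[a] == 1) return(1L)
    s <- unique(round(seq(1, vol_shape[a] - size[a] + 1,
                          length.out = grid[a])))
    as.integer(s)
  })
  if (any(vapply(starts, length, 1L) != grid))
    stop("block_grid: degenerate grid (blocks collapse); reduce grid or overlap")
  gap <- vapply(1:3, function(a)
    if (grid[a] == 1) 0 else max(diff(starts[[a]])), numeric(1))
  if (any(gap > size)) stop("block_grid: blocks do not cover the volume")
  structure(list(grid = as.integer(grid), size = as.integer(size),
                 starts = starts, n_blocks = prod(grid)),
            class = "block_grid")
}

#' Extract ordered blocks from a volume
#'
#' Deterministic z-major ordering (x index varies fastest, z slowest).
#' The union of the blocks covers every voxel.
#'
#' @param vol 3D array.
#' @param bg A [block_grid()] matching `dim(vol)`.
#' @return List of blocks, each with `data` (array), `start`, `index`.
#' @export
extract_blocks <- function(vol, bg) {
  stopifnot(inherits(bg, "block_grid"))
  if (any(vapply(1:3, function(a) max(bg$starts[[a]]) + bg$size[a] - 1, 1) >
          dim(vol)))
    stop("extract_blocks: grid does not fit the volume")
  combos <- expand.grid(x = bg$starts[[1]], y = bg$starts[[2]],
                        z = bg$starts[[3]])
  lapply(seq_len(nrow(combos)), function(i) {
    s <- as.integer(combos[i, ])
    list(data = vol[s[1]:(s[1] + bg$size[1] - 1),
                    s[2]:(s[2] + bg$size[2] - 1),
                    s[3]:(s[3] + bg$size[3] - 1), drop = FALSE],
         start = s, index = i)
  })
}

# block b of each listed volume, flattened into a (voxels x n) matrix
.block_matrix <- function(vols, bg, b) {
  combos <- expand.grid(x = bg$starts[[1]], y = bg$starts[[2]],
                        z = bg$starts[[3]])
  s <- as.integer(combos[b, ])
  vapply(vols, function(v)
    as.numeric(v[s[1]:(s[1] + bg$size[1] - 1),
                 s[2]:(s[2] + bg$size[2] - 1),
                 s[3]:(s[3] + bg$size[3] - 1)]),
    numeric(prod(bg$size)))
}

.translate <- function(vol, off) {
  d <- dim(vol)
  out <- array(0, d)
  src <- lapply(1:3, function(a) {
    r <- (1:d[a]) - off[a]
    r[r >= 1 & r <= d[a]]
  })
  dst <- lapply(1:3, function(a) {
    r <- (1:d[a])[(1:d[a]) - off[a] >= 1 & (1:d[a]) - off[a] <= d[a]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    vol[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

#' Eightfold shift augmentation of a training set
#'
#' Each training volume yields the 8 corner shifts `(+-s, +-s, +-s)`
#' (zero-filled at the trailing edge), so the training split grows by
#' exactly a factor of 8. Labels are preserved. Apply to training
#' splits only; validation and test data are never augmented.
#'
#' @param subjects List of subjects (each with `label` and one or more
#'   3D volume fields such as `mri`, `pet`), or a `volume_cohort`.
#' @param shift Shift magnitude in voxels (default 2). `shift = 0`
#'   degenerates to 8 identical copies and warns.
#' @return List of augmented subjects, `8 * length(subjects)` long.
#' @export
shift_augment <- function(subjects, shift = 2) {
  if (inherits(subjects, "volume_cohort")) subjects <- subjects$subjects
  if (shift == 0)
    warning("shift_augment: shift = 0 produces 8 identical copies")
  d <- dim(subjects[[1]][[intersect(c("mri", "pet"), names(subjects[[1]]))[1]]])
  if (shift >= min(d) / 2) {
    warning("shift_augment: shift exceeds volume margin; clamped")
    shift <- floor((min(d) - 1) / 2)
  }
  offs <- as.matrix(expand.grid(x = c(-shift, shift), y = c(-shift, shift),
                                z = c(-shift, shift)))
  out <- vector("list", 8 * length(subjects))
  k <- 0
  for (s in subjects) {
    for (r in seq_len(nrow(offs))) {
      k <- k + 1
      aug <- s
      for (mod in intersect(c("mri", "pet"), names(s)))
        aug[[mod]] <- .translate(s[[mod]], offs[r, ])
      aug$id <- sprintf("%s_shift%d", s$id, r)
      out[[k]] <- aug
    }
  }
  out
}

#' Cascade configuration
#'
#' Desk-scale defaults: 3 x 3 x 3 overlapping block grid, 2x mean
#' pooling inside each local net, one 3^3 conv layer of 4 channels and
#' an 8-unit hidden layer, 20 Adadelta epochs at batch 64, shift-2
#' eightfold augmentation, and an inner 20% validation split (not
#' augmented) for per-block accuracy ranking.
#'
#' @param grid Blocks per axis.
#' @param overlap Block overlap fraction.
#' @param channels Local-net conv channels.
#' @param hidden Local-net hidden (feature) width.
#' @param pool Pooling factor inside local nets.
#' @param fusion_channels Fusion-net conv channels.
#' @param epochs,batch_size Training protocol.
#' @param shift Augmentation shift in voxels.
#' @param inner_val Fraction of training subjects held out (unaugmented)
#'   for per-block validation accuracy.
#' @param modalities Modalities to use (`c("mri", "pet")`, or one).
#' @param train_baselines Also fit the four fusion baselines.
#' @param seed Seed for initialization, shuffling and splits.
#' @return A `cascade_config`.
#' @export
cascade_config <- function(grid = c(3, 3, 3), overlap = 0.5, channels = 4,
                           hidden = 8, pool = 2, fusion_channels = 8,
                           epochs = 20, batch_size = 64, shift = 2,
                           inner_val = 0.2, modalities = c("mri", "pet"),
                           train_baselines = TRUE, seed = 1) {
  structure(list(grid = grid, overlap = overlap, channels = channels,
                 hidden = hidden, pool = pool,
                 fusion_channels = fusion_channels, epochs = epochs,
                 batch_size = batch_size, shift = shift,
                 inner_val = inner_val, modalities = modalities,
                 train_baselines = train_baselines, seed = seed),
            class = "cascade_config")
}

#' Build a local 3D net for one image block
#'
#' Mean pooling, one 3^3 convolution with ReLU (its post-ReLU output is
#' the intermediate-feature tap used for fusion), then a hidden
#' fully-connected ReLU layer (the block's feature vector) and a
#' softmax classifier head.
#'
#' @param block_shape Block shape in voxels.
#' @param cfg A [cascade_config()].
#' @param classes Number of classes.
#' @param norm Optional input standardization, a list with `mu` (voxel
#'   mean vector) and `s` (scale), estimated from training data only.
#' @return An uninitialized `nn_model`; `meta$tap` and `meta$feat` hold
#'   the tap and feature layer indices, `meta$tap_sp`/`meta$tap_ch` the
#'   tap geometry.
#' @export
build_local_net <- function(block_shape, cfg = cascade_config(),
                            classes = 2, norm = NULL) {
  pool <- nn_pool(block_shape, 1, cfg$pool)
  sp <- pool$out_sp
  if (any(sp < 3))
    stop("build_local_net: block too small after pooling (",
         paste(sp, collapse = "x"), ")")
  conv <- nn_conv(sp, 1, cfg$channels, k = 3)
  sp2 <- conv$geom$out_sp
  layers <- list(pool, conv, nn_relu(prod(sp2) * cfg$channels),
                 nn_fc(prod(sp2) * cfg$channels, cfg$hidden),
                 nn_relu(cfg$hidden), nn_fc(cfg$hidden, classes))
  off <- 0
  if (!is.null(norm)) {
    layers <- c(list(nn_norm(norm$mu, norm$s, n = prod(block_shape))),
                layers)
    off <- 1
  }
  nn_model(layers, meta = list(tap = 3 + off, feat = 5 + off, tap_sp = sp2,
                               tap_ch = cfg$channels))
}

# permutation folding the 3rd spatial axis of a tap into channels:
# new 2D layout (x, y | z-within-channel) from 3D (x, y, z | channel)
.fold_perm <- function(sp, ch) {
  P3 <- prod(sp); P2 <- sp[1] * sp[2]
  idx <- integer(P3 * ch)
  pos2 <- seq_len(P2)
  k <- 0
  for (c in seq_len(ch)) for (z in seq_len(sp[3])) {
    idx[k * P2 + pos2] <- pos2 + (z - 1) * P2 + (c - 1) * P3
    k <- k + 1
  }
  idx
}

#' Build a per-location 2D fusion net
#'
#' Takes the two modalities' 3D tap feature maps at the same block,
#' folds the depth axis into channels, stacks the modalities
#' channelwise, and applies a small 2D conv + fully-connected net. The
#' hidden layer output is the fused per-location feature.
#'
#' @param tap_sp Tap spatial size (3D).
#' @param tap_ch Tap channels per modality.
#' @param cfg A [cascade_config()].
#' @param classes Number of classes.
#' @return An uninitialized `nn_model` with `meta$feat` marking the
#'   fused-feature layer and `meta$perm` the fold permutation.
#' @export
build_fusion_net <- function(tap_sp, tap_ch, cfg = cascade_config(),
                             classes = 2) {
  ch2d <- tap_sp[3] * tap_ch * 2
  sp2d <- tap_sp[1:2]
  k <- pmin(3, sp2d)
  conv <- nn_conv(sp2d, ch2d, cfg$fusion_channels, k = k)
  p2 <- prod(conv$geom$out_sp)
  layers <- list(conv, nn_relu(p2 * cfg$fusion_channels),
                 nn_fc(p2 * cfg$fusion_channels, cfg$hidden),
                 nn_relu(cfg$hidden), nn_fc(cfg$hidden, classes))
  nn_model(layers, meta = list(feat = 4, perm = .fold_perm(tap_sp, tap_ch)))
}

#' Fuse per-location modality features
#'
#' Reorganizes two modality tap matrices into the fusion net's 2D input
#' (depth folded into channels, modalities stacked channelwise).
#'
#' @param mri_tap,pet_tap `features x samples` tap matrices from the
#'   same block location and tap point.
#' @param fusion A [build_fusion_net()] model (provides the fold
#'   permutation and input contract).
#' @return Fusion-net input matrix.
#' @export
fuse_location <- function(mri_tap, pet_tap, fusion) {
  if (!identical(dim(mri_tap), dim(pet_tap)))
    stop("fuse_location: modality tap shapes differ")
  perm <- fusion$meta$perm
  X <- rbind(mri_tap[perm, , drop = FALSE], pet_tap[perm, , drop = FALSE])
  if (nrow(X) != fusion$layers[[1]]$in_dim)
    stop("fuse_location: tap does not match the fusion net input")
  X
}

#' Combine per-location features and classify
#'
#' Concatenates the per-location feature vectors in block order and
#' applies the fully-connected combiner; returns softmax class
#' probabilities.
#'
#' @param features List (one element per block location) of
#'   `features x samples` matrices; no location may be missing.
#' @param combiner The trained combiner `nn_model`.
#' @return `classes x samples` probability matrix (columns sum to 1).
#' @export
combine_and_classify <- function(features, combiner) {
  if (any(vapply(features, is.null, TRUE)))
    stop("combine_and_classify: missing block location(s): ",
         paste(which(vapply(features, is.null, TRUE)), collapse = ", "))
  X <- do.call(rbind, features)
  if (nrow(X) != combiner$layers[[1]]$in_dim)
    stop("combine_and_classify: feature length does not match the combiner")
  nn_predict(combiner, X)
}

# layer output for a batch, run in chunks
.layer_out <- function(model, X, layer, batch = 512) {
  n <- ncol(X); out <- NULL
  for (start in seq(1, n, by = batch)) {
    sel <- start:min(start + batch - 1, n)
    a <- nn_forward(model, X[, sel, drop = FALSE])$acts[[layer]]
    out <- if (is.null(out)) a else cbind(out, a)
  }
  out
}

# combiner/baseline heads are tiny; give them enough Adadelta steps to
# converge even when a training fold holds only a few dozen samples
.fit_head <- function(X, y, classes, cfg, seed_off = 0) {
  head <- nn_model(list(nn_fc(nrow(X), classes)))
  head <- nn_init_xavier(head, seed = cfg$seed + seed_off)
  epochs <- max(3 * cfg$epochs, ceiling(4000 / max(1, ncol(X))))
  nn_train(head, X, y, train_config(epochs = epochs,
                                    batch_size = min(cfg$batch_size, 32),
                                    seed = cfg$seed + seed_off))
}

.labels_to_int <- function(labels, levels) match(labels, levels)

#' Train the cascaded classifier on a training split
#'
#' Fits, per modality and block, a local 3D net on the (shift-
#' augmented) training subjects; per block, a 2D fusion net over both
#' modalities' tap features; and fully-connected combiners over the
#' per-location features (one fused, one per modality). Per-block
#' validation accuracies come from an inner unaugmented holdout.
#' Optionally also fits the four fusion baselines (average, concat,
#' parallel, bilinear).
#'
#' @param subjects Training subjects (list with `label` and modality
#'   volumes).
#' @param levels Class labels, length 2 (first = negative/control).
#' @param cfg A [cascade_config()].
#' @return A `cascade_model` bundle.
#' @export
cascade_fit <- function(subjects, levels, cfg = cascade_config()) {
  y_all <- .labels_to_int(vapply(subjects, `[[`, "", "label"), levels)
  stopifnot(!anyNA(y_all))
  d <- dim(subjects[[1]][[cfg$modalities[1]]])
  bg <- block_grid(d, cfg$grid, cfg$overlap)
  set.seed(cfg$seed)
  # inner stratified holdout for block ranking (kept unaugmented)
  val_idx <- unlist(lapply(unique(y_all), function(cl) {
    ids <- which(y_all == cl)
    sample(ids, max(1, round(cfg$inner_val * length(ids))))
  }))
  tr_subj <- subjects[-val_idx]
  aug <- shift_augment(tr_subj, cfg$shift)
  y_tr <- .labels_to_int(vapply(aug, `[[`, "", "label"), levels)
  y_val <- y_all[val_idx]
  proto <- build_local_net(bg$size, cfg, classes = 2)
  local <- list(); val_acc <- list()
  tap_tr <- list(); tap_val <- list(); feat_tr <- list(); feat_val <- list()
  gap_tr <- list(); gap_val <- list()
  for (mod in cfg$modalities) {
    vols_tr <- lapply(aug, `[[`, mod)
    vols_val <- lapply(subjects[val_idx], `[[`, mod)
    local[[mod]] <- vector("list", bg$n_blocks)
    val_acc[[mod]] <- numeric(bg$n_blocks)
    tap_tr[[mod]] <- vector("list", bg$n_blocks)
    tap_val[[mod]] <- vector("list", bg$n_blocks)
    feat_tr[[mod]] <- vector("list", bg$n_blocks)
    feat_val[[mod]] <- vector("list", bg$n_blocks)
    gap_tr[[mod]] <- vector("list", bg$n_blocks)
    gap_val[[mod]] <- vector("list", bg$n_blocks)
    for (b in seq_len(bg$n_blocks)) {
      Xb <- .block_matrix(vols_tr, bg, b)
      net <- build_local_net(bg$size, cfg, classes = 2,
                             norm = list(mu = rowMeans(Xb),
                                         s = stats::sd(Xb)))
      net <- nn_init_xavier(net, seed = cfg$seed + 1000 * match(mod, cfg$modalities) + b)
      net <- nn_train(net, Xb, y_tr,
                      train_config(epochs = cfg$epochs,
                                   batch_size = cfg$batch_size,
                                   seed = cfg$seed + b))
      local[[mod]][[b]] <- net
      Xv <- .block_matrix(vols_val, bg, b)
      val_acc[[mod]][b] <- nn_accuracy(net, Xv, y_val)
      tap_tr[[mod]][[b]] <- .layer_out(net, Xb, net$meta$tap)
      tap_val[[mod]][[b]] <- .layer_out(net, Xv, net$meta$tap)
      feat_tr[[mod]][[b]] <- .layer_out(net, Xb, net$meta$feat)
      feat_val[[mod]][[b]] <- .layer_out(net, Xv, net$meta$feat)
      P3 <- prod(proto$meta$tap_sp)
      gap_tr[[mod]][[b]] <- .tap_gap(tap_tr[[mod]][[b]], P3, cfg$channels)
      gap_val[[mod]][[b]] <- .tap_gap(tap_val[[mod]][[b]], P3, cfg$channels)
    }
  }
  multimodal <- length(cfg$modalities) == 2
  fusion <- NULL; fused_tr <- NULL
  if (multimodal) {
    fusion <- vector("list", bg$n_blocks)
    fused_tr <- vector("list", bg$n_blocks)
    for (b in seq_len(bg$n_blocks)) {
      fnet <- build_fusion_net(proto$meta$tap_sp, proto$meta$tap_ch, cfg)
      fnet <- nn_init_xavier(fnet, seed = cfg$seed + 5000 + b)
      Xf <- fuse_location(tap_tr[["mri"]][[b]], tap_tr[["pet"]][[b]], fnet)
      fnet <- nn_train(fnet, Xf, y_tr,
                       train_config(epochs = cfg$epochs,
                                    batch_size = cfg$batch_size,
                                    seed = cfg$seed + 5000 + b))
      fusion[[b]] <- fnet
      fused_tr[[b]] <- .layer_out(fnet, Xf, fnet$meta$feat)
    }
  }
  combiners <- list()
  for (mod in cfg$modalities)
    combiners[[mod]] <- .fit_head(do.call(rbind, feat_tr[[mod]]), y_tr, 2,
                                  cfg, seed_off = 7000 + match(mod, cfg$modalities))
  if (multimodal)
    combiners$fused <- .fit_head(do.call(rbind, fused_tr), y_tr, 2, cfg,
                                 seed_off = 7100)
  baselines <- NULL
  if (multimodal && cfg$train_baselines) {
    baselines <- list(
      concat = .fit_head(rbind(do.call(rbind, feat_tr$mri),
                               do.call(rbind, feat_tr$pet)),
                         y_tr, 2, cfg, seed_off = 7200),
      parallel = .fit_head(rbind(do.call(rbind, gap_tr$mri),
                                 do.call(rbind, gap_tr$pet)),
                           y_tr, 2, cfg, seed_off = 7300),
      bilinear = .fit_head(.bilinear_features(feat_tr$mri, feat_tr$pet),
                           y_tr, 2, cfg, seed_off = 7400))
  }
  structure(list(bg = bg, cfg = cfg, levels = levels, local = local,
                 fusion = fusion, combiners = combiners,
                 baselines = baselines, val_acc = val_acc,
                 tap_sp = proto$meta$tap_sp, tap_ch = proto$meta$tap_ch),
            class = "cascade_model")
}

# channelwise global average of a tap matrix: (P3 * ch) x B -> ch x B
.tap_gap <- function(tap, P3, ch) {
  a <- array(tap, c(P3, ch * ncol(tap)))
  matrix(colMeans(a), ch, ncol(tap))
}

# per-block outer products of the two modalities' feature vectors,
# averaged over blocks ("bilinear point multiplication")
.bilinear_features <- function(fa, fb) {
  B <- ncol(fa[[1]]); k <- nrow(fa[[1]])
  out <- matrix(0, k * k, B)
  for (b in seq_along(fa))
    for (j in seq_len(B))
      out[, j] <- out[, j] + as.numeric(outer(fa[[b]][, j], fb[[b]][, j]))
  out / length(fa)
}

#' Predict with a trained cascade
#'
#' Runs every requested subject through the local nets, fusion nets and
#' combiners, returning class-probability matrices for the fused
#' cascade, each single modality, and (when trained) the four fusion
#' baselines.
#'
#' @param model A [cascade_fit()] bundle.
#' @param subjects List of subjects with the model's modalities.
#' @return Named list of `2 x n` probability matrices.
#' @export
cascade_predict <- function(model, subjects) {
  cfg <- model$cfg; bg <- model$bg
  taps <- list(); feats <- list(); gaps <- list()
  for (mod in cfg$modalities) {
    vols <- lapply(subjects, `[[`, mod)
    taps[[mod]] <- vector("list", bg$n_blocks)
    feats[[mod]] <- vector("list", bg$n_blocks)
    gaps[[mod]] <- vector("list", bg$n_blocks)
    for (b in seq_len(bg$n_blocks)) {
      Xb <- .block_matrix(vols, bg, b)
      net <- model$local[[mod]][[b]]
      taps[[mod]][[b]] <- .layer_out(net, Xb, net$meta$tap)
      feats[[mod]][[b]] <- .layer_out(net, Xb, net$meta$feat)
      gaps[[mod]][[b]] <- .tap_gap(taps[[mod]][[b]], prod(model$tap_sp),
                                   model$tap_ch)
    }
  }
  out <- list()
  for (mod in cfg$modalities)
    out[[mod]] <- combine_and_classify(feats[[mod]], model$combiners[[mod]])
  if (!is.null(model$fusion)) {
    fused_feats <- lapply(seq_len(bg$n_blocks), function(b) {
      fnet <- model$fusion[[b]]
      Xf <- fuse_location(taps$mri[[b]], taps$pet[[b]], fnet)
      .layer_out(fnet, Xf, fnet$meta$feat)
    })
    out$fused <- combine_and_classify(fused_feats, model$combiners$fused)
    out$average <- (out$mri + out$pet) / 2
    if (!is.null(model$baselines)) {
      out$concat <- nn_predict(model$baselines$concat,
                               rbind(do.call(rbind, feats$mri),
                                     do.call(rbind, feats$pet)))
      out$parallel <- nn_predict(model$baselines$parallel,
                                 rbind(do.call(rbind, gaps$mri),
                                       do.call(rbind, gaps$pet)))
      out$bilinear <- nn_predict(model$baselines$bilinear,
                                 .bilinear_features(feats$mri, feats$pet))
    }
  } else {
    out$fused <- out[[cfg$modalities[1]]]
  }
  out
}

#' Transfer-initialize a model from a source task
#'
#' Copies weights layer by layer between architecturally identical
#' models (errors on any shape mismatch). For cascade bundles, local
#' and fusion nets are copied and the combiners are re-initialized, the
#' protocol used along the easy-to-hard task chain (AD/NC initializes
#' pMCI/NC, which initializes sMCI/NC).
#'
#' @param target Model or `cascade_model` to initialize.
#' @param source Trained model of the same architecture.
#' @return `target` with copied weights.
#' @export
transfer_init <- function(target, source) {
  if (inherits(target, "cascade_model")) {
    stopifnot(inherits(source, "cascade_model"))
    for (mod in names(target$local))
      for (b in seq_along(target$local[[mod]]))
        target$local[[mod]][[b]] <-
          transfer_init(target$local[[mod]][[b]], source$local[[mod]][[b]])
    if (!is.null(target$fusion))
      for (b in seq_along(target$fusion))
        target$fusion[[b]] <- transfer_init(target$fusion[[b]],
                                            source$fusion[[b]])
    for (nm in names(target$combiners))
      target$combiners[[nm]] <-
        nn_init_xavier(target$combiners[[nm]],
                       seed = target$cfg$seed + 9000 + match(nm, names(target$combiners)))
    return(target)
  }
  stopifnot(length(target$layers) == length(source$layers))
  for (i in seq_along(target$layers)) {
    if (is.null(target$layers[[i]]$W)) next
    if (!identical(dim(target$layers[[i]]$W), dim(source$layers[[i]]$W)))
      stop("transfer_init: layer ", i, " shape mismatch")
    target$layers[[i]]$W <- source$layers[[i]]$W
    target$layers[[i]]$b <- source$layers[[i]]$b
  }
  target
}

#' Stratified cross-validation plan
#'
#' Partitions subjects into `folds` label-stratified folds; every
#' subject appears in exactly one fold, so no subject leaks between a
#' training and its test split.
#'
#' @param labels Subject labels.
#' @param folds Fold count (default 10).
#' @param seed RNG seed; assignments are reproducible.
#' @return Integer fold assignment per subject.
#' @export
cv_plan <- function(labels, folds = 10, seed = 1) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    if (length(ids) < folds)
      stop("cv_plan: class ", cl, " has fewer subjects (", length(ids),
           ") than folds (", folds, ")")
    assign[ids] <- sample(rep_len(seq_len(folds), length(ids)))
  }
  assign
}

.binary_metrics <- function(y_true, p_pos, positive = 2) {
  pred <- ifelse(p_pos > 0.5, 2, 1)
  acc <- mean(pred == y_true)
  sens <- mean(pred[y_true == 2] == 2)
  spec <- mean(pred[y_true == 1] == 1)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y_true,
                                        predictor = p_pos,
                                        levels = c(1, 2),
                                        direction = "<", quiet = TRUE)))
  c(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

#' Cross-validated cascade evaluation
#'
#' Runs stratified k-fold cross-validation of the cascade on a volume
#' cohort. Augmentation and all model fitting happen strictly inside
#' each training fold; test folds are never augmented. Metrics
#' (accuracy, sensitivity, specificity, AUC) are computed from the
#' pooled out-of-fold probabilities, for the fused cascade, each single
#' modality, and the fusion baselines.
#'
#' @param cohort A [gen_volume_cohort()] cohort (or subject list).
#' @param task `"ad-nc"`, `"pmci-nc"` or `"smci-nc"`; the MCI-based
#'   tasks use the synthetic MCI group as the disease surrogate.
#' @param folds Fold count (default 10).
#' @param cfg A [cascade_config()].
#' @param seed Fold-assignment seed.
#' @param permute_labels Permute labels before CV (permutation null).
#' @return List with `metrics` (matrix, one row per method), `probs`
#'   (pooled positive-class probabilities), `y`, `fold`, `levels`.
#' @export
run_cv <- function(cohort, task = "ad-nc", folds = 10,
                   cfg = cascade_config(), seed = 1,
                   permute_labels = FALSE) {
  subjects <- if (inherits(cohort, "volume_cohort")) cohort$subjects else cohort
  levels <- switch(task, "ad-nc" = c("NC", "AD"),
                   "pmci-nc" = c("NC", "MCI"), "smci-nc" = c("NC", "MCI"),
                   stop("run_cv: unknown task ", task))
  subjects <- Filter(function(s) s$label %in% levels, subjects)
  labels <- vapply(subjects, `[[`, "", "label")
  if (permute_labels) {
    set.seed(seed + 777)
    labels <- sample(labels)
    for (i in seq_along(subjects)) subjects[[i]]$label <- labels[i]
  }
  fold <- cv_plan(labels, folds, seed)
  y <- .labels_to_int(labels, levels)
  probs <- NULL
  for (f in sort(unique(fold))) {
    tr <- subjects[fold != f]
    te <- subjects[fold == f]
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f
    mdl <- cascade_fit(tr, levels, cfg_f)
    pr <- cascade_predict(mdl, te)
    pos <- lapply(pr, function(p) p[2, ])
    if (is.null(probs))
      probs <- stats::setNames(vector("list", length(pos)), names(pos))
    for (nm in names(pos)) {
      v <- numeric(length(subjects)) * NA
      v[fold == f] <- pos[[nm]]
      probs[[nm]] <- if (is.null(probs[[nm]])) v
                     else ifelse(is.na(probs[[nm]]), v, probs[[nm]])
    }
  }
  metrics <- t(vapply(probs, function(p) .binary_metrics(y, p),
                      c(accuracy = 0, sensitivity = 0, specificity = 0,
                        auc = 0)))
  list(metrics = metrics, probs = probs, y = y, fold = fold,
       levels = levels)
}

#' Fusion baseline classifier from trained single-modality nets
#'
#' The four reference fusion strategies: `average` (mean of the two
#' modality probability outputs), `concat` (joined fully-connected
#' features re-classified), `parallel` (last-conv features joined
#' channelwise, then classified), `bilinear` (per-block outer products
#' of the fully-connected features, averaged over blocks, then
#' classified). `average` needs no training; the others are fitted
#' heads stored in the cascade bundle.
#'
#' @param model A trained [cascade_fit()] bundle with baselines.
#' @param mode One of `"average"`, `"concat"`, `"parallel"`,
#'   `"bilinear"`.
#' @param subjects Subjects to classify.
#' @return `2 x n` probability matrix.
#' @export
fusion_baseline <- function(model, mode, subjects) {
  mode <- match.arg(mode, c("average", "concat", "parallel", "bilinear"))
  pr <- cascade_predict(model, subjects)
  if (is.null(pr[[mode]]))
    stop("fusion_baseline: bundle was trained without baselines")
  pr[[mode]]
}
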