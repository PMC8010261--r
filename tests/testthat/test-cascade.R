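nc <- asNamespace("neurocascade")

test_that("crop-and-downsample removes empty margins and hits the target shape", {
  v <- array(0, c(64, 60, 56))
  v[21:44, 21:40, 21:40] <- 1 + array(runif(24 * 20 * 20), c(24, 20, 20))
  out <- crop_and_downsample(v, target = c(10, 9, 8))
  expect_equal(dim(out), c(10, 9, 8))
  # tight box without a target: downsampled nonzero extent only
  tight <- crop_and_downsample(v, target = NULL)
  expect_equal(dim(tight), c(12, 10, 10))
  # constant volume downsamples to the same constant
  cv <- crop_and_downsample(array(3, c(8, 8, 8)), target = NULL)
  expect_true(all(cv == 3))
  expect_equal(dim(cv), c(4, 4, 4))
  expect_error(crop_and_downsample(array(0, c(8, 8, 8))), "empty")
})

test_that("the default grid yields 27 covering blocks in z-major order", {
  bg <- block_grid(c(25, 21, 20))
  expect_equal(bg$n_blocks, 27)
  v <- array(seq_len(25 * 21 * 20), c(25, 21, 20))
  blocks <- extract_blocks(v, bg)
  expect_length(blocks, 27)
  # coverage: every voxel belongs to at least one block
  covered <- array(FALSE, dim(v))
  for (b in blocks) {
    s <- b$start
    covered[s[1]:(s[1] + bg$size[1] - 1), s[2]:(s[2] + bg$size[2] - 1),
            s[3]:(s[3] + bg$size[3] - 1)] <- TRUE
  }
  expect_true(all(covered))
  # z-major: x start varies fastest
  expect_equal(blocks[[2]]$start[2:3], blocks[[1]]$start[2:3])
  expect_true(blocks[[2]]$start[1] > blocks[[1]]$start[1])
  # 1x1x1 grid returns the whole volume
  whole <- extract_blocks(v, block_grid(dim(v), grid = c(1, 1, 1)))
  expect_identical(whole[[1]]$data, v)
  expect_error(block_grid(c(5, 5, 5), grid = c(6, 1, 1)), "larger")
})

test_that("shift augmentation multiplies the training split by exactly 8", {
  spec <- cohort_spec(n_per_group = c(AD = 5, NC = 5), seed = 14)
  coh <- gen_volume_cohort(volume_spec(seed = 14), spec)
  aug <- shift_augment(coh, 2)
  expect_length(aug, 8 * 10)
  expect_equal(vapply(aug, `[[`, "", "label"),
               rep(vapply(coh$subjects, `[[`, "", "label"), each = 8))
  # the 8 variants are distinct shifts of the same volume
  expect_false(identical(aug[[1]]$mri, aug[[2]]$mri))
  expect_equal(sort(unique(as.numeric(aug[[1]]$mri - aug[[2]]$mri) == 0)),
               c(FALSE, TRUE))
  expect_warning(shift_augment(coh$subjects[1], 0), "identical copies")
  expect_warning(shift_augment(coh$subjects[1], 50), "clamped")
})

test_that("stratified CV folds partition subjects reproducibly", {
  labels <- rep(c("AD", "NC"), c(12, 14))
  f1 <- cv_plan(labels, folds = 5, seed = 3)
  f2 <- cv_plan(labels, folds = 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, cv_plan(labels, folds = 5, seed = 4)))
  expect_setequal(unique(f1), 1:5)
  # stratification: each fold holds 2-3 AD and 2-3 NC
  tab <- table(labels, f1)
  expect_true(all(tab >= 2 & tab <= 3))
  expect_error(cv_plan(rep(c("AD", "NC"), c(3, 20)), folds = 5), "fewer")
})

test_that("combiner and fusion plumbing enforce their contracts", {
  comb <- nc$nn_model(list(nc$nn_fc(12, 2)))
  comb <- nc$nn_init_xavier(comb, seed = 2)
  feats <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2),
                matrix(rnorm(8), 4, 2))
  p <- combine_and_classify(feats, comb)
  expect_equal(colSums(p), c(1, 1))
  expect_error(combine_and_classify(list(feats[[1]], NULL, feats[[3]]), comb),
               "missing")
  expect_error(combine_and_classify(feats[1:2], comb), "feature length")
  # zero-weight combiner is indifferent: uniform probabilities
  comb0 <- nc$nn_model(list(nc$nn_fc(12, 2)))
  expect_equal(as.numeric(combine_and_classify(feats, comb0)),
               rep(0.5, 4))
  fus <- build_fusion_net(c(4, 3, 3), 4, cascade_config())
  tap <- matrix(rnorm(4 * 3 * 3 * 4 * 5), 144, 5)
  X <- fuse_location(tap, tap, fus)
  expect_equal(nrow(X), fus$layers[[1]]$in_dim)
  # identical modalities: the two channel halves coincide
  expect_identical(X[1:144, ], X[145:288, ])
  expect_error(fuse_location(tap, tap[, 1:2], fus), "differ")
})

test_that("transfer initialization copies weights exactly or refuses", {
  m1 <- nc$nn_init_xavier(nc$nn_model(list(nc$nn_fc(10, 4), nc$nn_relu(4),
                                           nc$nn_fc(4, 2))), seed = 1)
  m2 <- nc$nn_init_xavier(nc$nn_model(list(nc$nn_fc(10, 4), nc$nn_relu(4),
                                           nc$nn_fc(4, 2))), seed = 2)
  t1 <- transfer_init(m2, m1)
  expect_identical(t1$layers, m1$layers)
  X <- matrix(rnorm(30), 10, 3)
  expect_identical(nc$nn_predict(t1, X), nc$nn_predict(m1, X))
  m3 <- nc$nn_model(list(nc$nn_fc(10, 5), nc$nn_relu(5), nc$nn_fc(5, 2)))
  expect_error(transfer_init(m3, m1), "shape mismatch")
})

test_that("a separable toy cohort reaches ceiling AUC under tiny CV", {
  # near-noiseless, high-contrast volumes: the degenerate easy case
  vs <- volume_spec(shape = c(12, 10, 10),
                    lesion_centers = list(mri = matrix(c(4, 4, 5), 1),
                                          pet = matrix(c(9, 7, 5), 1)),
                    lesion_radius = 2, class_contrast = 3, noise_sd = 0.05,
                    seed = 15)
  coh <- gen_volume_cohort(vs, cohort_spec(n_per_group = c(AD = 6, NC = 6),
                                           seed = 15))
  cfg <- cascade_config(grid = c(1, 1, 1), modalities = "mri",
                        train_baselines = FALSE, epochs = 10, shift = 1,
                        seed = 15)
  cv <- run_cv(coh, task = "ad-nc", folds = 3, cfg = cfg, seed = 15)
  expect_equal(unname(cv$metrics["mri", "auc"]), 1)
  expect_gte(unname(cv$metrics["mri", "accuracy"]), 0.8)
  # fold assignment is reproducible and leak-free by construction
  cv2 <- run_cv(coh, task = "ad-nc", folds = 3, cfg = cfg, seed = 15)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$probs, cv2$probs)
})
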