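# Seeded experiment drivers. These wrap the package's modules into the
# reference experiments reported in the README/vignette: planted-effect
# recovery and null calibration for t-test feature selection,
# desk-scale cascade cross-validation with fusion baselines,
# permutation-null AUC, pruning forward-equivalence, and occlusion
# localization. All are deterministic given their seed.

#' Planted-effect recovery of t-test feature selection
#'
#' Replicated recovery experiment at the reference conditions: 52
#' regions, 30 subjects per group (AD vs NC), effect size 1.5. A
#' replicate "recovers" when every effect node contributes at least one
#' selected feature; the recovery rate is the fraction of replicates
#' that do.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed (replicate r uses `seed + r`).
#' @param effect_size Planted standardized effect.
#' @param n_per_group Subjects per group.
#' @param alpha Selection level.
#' @return List: `recovery_rate`, per-replicate `recovered`, and the
#'   mean selected fraction `selected_frac`.
#' @export
experiment_selection_recovery <- function(n_rep = 50, seed = 0,
                                          effect_size = 1.5,
                                          n_per_group = 30, alpha = 0.05) {
  recovered <- logical(n_rep)
  sel_frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(n_per_group = c(AD = n_per_group, NC = n_per_group),
                        effect_size = effect_size, seed = seed + r)
    fx <- cohort_features(spec)
    sel <- ttest_select(fx$features[fx$labels == "AD", , drop = FALSE],
                        fx$features[fx$labels == "NC", , drop = FALSE],
                        alpha = alpha)
    sel_frac[r] <- mean(sel$selected)
    # a feature belongs to node v if it is v's degree/efficiency/
    # betweenness in either network
    node_of <- as.integer(sub(".*\\.", "", sel$feature))
    hit <- vapply(spec$effect_nodes, function(v)
      any(sel$selected & node_of == v), logical(1))
    recovered[r] <- all(hit)
  }
  list(recovery_rate = mean(recovered), recovered = recovered,
       selected_frac = mean(sel_frac))
}

#' Null-cohort selection-rate calibration
#'
#' With no planted effect the data are label-exchangeable, so the
#' fraction of features selected at level alpha estimates the type-I
#' rate. Uses a reduced cohort (20 regions, 10 per group, 60
#' timepoints) so many replicates stay fast.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param alpha Selection level.
#' @return List: `mean_selected_frac`, per-replicate `selected_frac`.
#' @export
experiment_null_selection <- function(n_rep = 200, seed = 1, alpha = 0.05) {
  frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(n_per_group = c(AD = 10, NC = 10), n_regions = 20,
                        n_timepoints = 60, effect_nodes = integer(0),
                        effect_size = 0, seed = seed + r)
    fx <- cohort_features(spec)
    sel <- ttest_select(fx$features[fx$labels == "AD", , drop = FALSE],
                        fx$features[fx$labels == "NC", , drop = FALSE],
                        alpha = alpha)
    frac[r] <- mean(sel$selected)
  }
  list(mean_selected_frac = mean(frac), selected_frac = frac)
}

#' Default desk-scale multimodal cohort
#'
#' The reference synthetic cohort for cascade experiments: 20 AD and
#' 20 NC subjects with 25 x 21 x 20 volume pairs and modality-specific
#' lesions.
#'
#' @param seed Cohort seed.
#' @param n_per_group Subjects per group.
#' @return A `volume_cohort`.
#' @export
default_volume_cohort <- function(seed = 0, n_per_group = c(AD = 20, NC = 20)) {
  gen_volume_cohort(volume_spec(seed = seed),
                    cohort_spec(n_per_group = n_per_group, seed = seed))
}

#' Desk-scale cascade cross-validation experiment
#'
#' Ten-fold stratified CV of the cascaded multimodal classifier on the
#' default synthetic cohort, with single-modality cascades and the four
#' fusion baselines evaluated on the same folds.
#'
#' @param seed Cohort and fold seed.
#' @param folds Fold count.
#' @param cfg A [cascade_config()].
#' @return The [run_cv()] result.
#' @export
experiment_cascade <- function(seed = 0, folds = 10,
                               cfg = cascade_config(seed = seed)) {
  cohort <- default_volume_cohort(seed = seed)
  run_cv(cohort, task = "ad-nc", folds = folds, cfg = cfg, seed = seed)
}

#' Permutation-null AUC of the cascade CV harness
#'
#' Repeats label-permuted cross-validation on a scaled-down protocol
#' (single modality, one whole-volume block, 5 folds) and reports the
#' AUC distribution, which must center near 0.5 if no information
#' leaks between training and test folds.
#'
#' @param n_seeds Number of permutation runs.
#' @param seed Base seed.
#' @return List: `mean_auc`, per-run `auc`.
#' @export
experiment_permutation_auc <- function(n_seeds = 20, seed = 0) {
  aucs <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    cohort <- default_volume_cohort(seed = seed + 100 + r)
    cfg <- cascade_config(grid = c(1, 1, 1), modalities = "mri",
                          train_baselines = FALSE, epochs = 8,
                          seed = seed + r)
    cv <- run_cv(cohort, task = "ad-nc", folds = 5, cfg = cfg,
                 seed = seed + r, permute_labels = TRUE)
    aucs[r] <- cv$metrics["mri", "auc"]
  }
  list(mean_auc = mean(aucs), auc = aucs)
}

#' Masked-versus-materialized pruning equivalence
#'
#' Over `n` random (model, plan, input) triples: builds a random
#' separable net, plans a random pruning ratio, masks, materializes,
#' and compares the two forward passes; also checks that the pruned
#' unit's depthwise + pointwise mult-adds equal `(1 - epsilon)` times
#' the unpruned unit's when `M * epsilon` is integral.
#'
#' @param n Number of triples.
#' @param seed Base seed.
#' @return List: `max_abs_diff` (forward outputs), `max_cost_err`
#'   (relative cost-ratio error), `n`.
#' @export
experiment_pruning_equivalence <- function(n = 100, seed = 0) {
  max_diff <- 0; max_cost <- 0
  for (r in seq_len(n)) {
    set.seed(seed + r)
    M <- sample(c(4L, 8L), 1)
    model <- build_sepnet(input_sp = c(10, 10), stem_channels = M,
                          unit_channels = c(M, sample(c(4L, 8L), 1)),
                          classes = 2, seed = seed + r)
    eps <- sample(c(0.25, 0.5), 1)
    X <- matrix(stats::rnorm(100 * 8), 100, 8)
    apoz <- collect_activations(model, X)
    plan <- rank_and_select(apoz, eps)
    masked <- mask_unit(model, plan)
    small <- materialize(masked)
    d <- max(abs(nn_forward(masked, X)$out - nn_forward(small, X)$out))
    max_diff <- max(max_diff, d)
    # unit-2 cost ratio against the closed form
    u <- model$meta$units[[2]]
    unit_ma <- function(m) {
      model_multadds(m, by_layer = TRUE)[c(u$D, u$P)]
    }
    ratio <- sum(unit_ma(small)) / sum(unit_ma(model))
    max_cost <- max(max_cost, abs(ratio - (1 - eps)))
  }
  list(max_abs_diff = max_diff, max_cost_err = max_cost, n = n)
}

#' Toy image classes for pruning experiments
#'
#' Two-class 2D images: a bright Gaussian blob on the left (class 1) or
#' right (class 2) half, plus noise.
#'
#' @param n Samples per class.
#' @param sp Image size.
#' @param noise_sd Noise scale.
#' @param seed RNG seed.
#' @return List: `X` (pixels x 2n), `y` (labels 1/2).
#' @export
gen_toy_images <- function(n = 100, sp = c(12, 12), noise_sd = 0.6,
                           seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(sp[1]), y = seq_len(sp[2]))
  blob <- function(cx, cy)
    exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * 2^2))
  y <- rep(1:2, each = n)
  X <- vapply(y, function(cl) {
    cx <- if (cl == 1) sp[1] * 0.3 else sp[1] * 0.7
    blob(cx + stats::rnorm(1, 0, 0.5), sp[2] / 2 + stats::rnorm(1, 0, 0.5)) +
      stats::rnorm(nrow(g), 0, noise_sd)
  }, numeric(prod(sp)))
  list(X = X, y = y)
}

#' Prune-and-finetune accuracy experiment
#'
#' Trains a separable toy net, prunes at ratio `epsilon` with the
#' requested schedule, fine-tunes, and reports test accuracies before
#' and after.
#'
#' @param epsilon Pruning ratio.
#' @param schedule `"greedy"` or `"layerwise"`.
#' @param seed RNG seed.
#' @param epochs Training epochs (fine-tuning uses half).
#' @return List with `acc_before`, `acc_after`, `multadds_before`,
#'   `multadds_after`, `params_before`, `params_after`.
#' @export
experiment_prune_finetune <- function(epsilon = 0.25,
                                      schedule = c("greedy", "layerwise"),
                                      seed = 0, epochs = 25) {
  schedule <- match.arg(schedule)
  train <- gen_toy_images(150, seed = seed + 1)
  test <- gen_toy_images(100, seed = seed + 2)
  model <- build_sepnet(stem_channels = 8, unit_channels = c(8, 8),
                        seed = seed)
  model <- nn_train(model, train$X, train$y,
                    train_config(epochs = epochs, seed = seed))
  acc_before <- nn_accuracy(model, test$X, test$y)
  cfg <- train_config(epochs = ceiling(epochs / 2), seed = seed + 3)
  rep <- if (schedule == "greedy")
    greedy_schedule(model, train$X, train$y, epsilon, cfg)
  else layerwise_schedule(model, train$X, train$y, epsilon, cfg)
  list(acc_before = acc_before,
       acc_after = nn_accuracy(rep$model, test$X, test$y),
       multadds_before = rep$multadds_before,
       multadds_after = rep$multadds_after,
       params_before = rep$params_before,
       params_after = rep$params_after,
       plan = rep$plan, apoz = rep$apoz, model = rep$model)
}

#' Occlusion localization experiment
#'
#' Per seed: generate a small cohort, train a whole-volume 3D net on
#' the MRI channel, compute occlusion maps for 10 held-out AD subjects,
#' aggregate, and test whether the aggregate map's argmax center falls
#' inside the planted MRI lesion. Reports the hit rate over seeds.
#'
#' @param n_seeds Number of independent seeds.
#' @param seed Base seed.
#' @param n_train Training subjects per group.
#' @return List: `hit_rate`, per-seed `hits`, `dist` (argmax-to-center
#'   distances).
#' @export
experiment_saliency_localization <- function(n_seeds = 20, seed = 0,
                                             n_train = 12) {
  hits <- logical(n_seeds); dist <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    vs <- volume_spec(seed = seed + r)
    cohort <- gen_volume_cohort(vs,
      cohort_spec(n_per_group = c(AD = n_train + 10, NC = n_train),
                  seed = seed + r))
    subs <- cohort$subjects
    lab <- vapply(subs, `[[`, "", "label")
    ad <- which(lab == "AD"); nc <- which(lab == "NC")
    test_ad <- ad[seq_len(10)]
    train <- subs[c(setdiff(ad, test_ad), nc)]
    aug <- shift_augment(train, 2)
    y <- .labels_to_int(vapply(aug, `[[`, "", "label"), c("NC", "AD"))
    X <- vapply(aug, function(s) as.numeric(s$mri),
                numeric(prod(vs$shape)))
    net <- build_local_net(vs$shape, cascade_config(seed = seed + r),
                           norm = list(mu = rowMeans(X), s = stats::sd(X)))
    net <- nn_init_xavier(net, seed = seed + r)
    net <- nn_train(net, X, y, train_config(epochs = 30, seed = seed + r))
    # gray in the model's standardized space: the train-mean template
    template <- array(rowMeans(X), vs$shape)
    maps <- lapply(subs[test_ad], function(s)
      occlusion_map(net, s$mri, occlusion_spec(fill = "reference"),
                    class_idx = 2, reference = template))
    agg <- aggregate_maps(maps, top_k = 1)
    top <- as.numeric(agg$ranked[1, c("x", "y", "z")])
    truth <- vs$lesion_centers$mri[1, ]
    dist[r] <- sqrt(sum((top - truth)^2))
    hits[r] <- dist[r] <= vs$lesion_radius
  }
  list(hit_rate = mean(hits), hits = hits, dist = dist)
}
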