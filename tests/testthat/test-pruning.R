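nc <- asNamespace("neurocascade")

test_that("APoZ measures the exact zero fraction per depthwise channel", {
  model <- build_sepnet(input_sp = c(8, 8), stem_channels = 4,
                        unit_channels = c(4, 4), seed = 10)
  set.seed(10)
  X <- matrix(rnorm(64 * 12), 64, 12)
  tab <- collect_activations(model, X)
  expect_s3_class(tab, "apoz_table")
  expect_true(all(tab$apoz >= 0 & tab$apoz <= 1))
  expect_equal(nrow(tab), 8)  # 4 channels x 2 units
  # oracle: recompute the zero fraction straight from the forward pass
  fwd <- nc$nn_forward(model, X)
  u1 <- model$meta$units[[1]]
  P <- model$layers[[u1$D]]$geom$P
  A <- fwd$acts[[u1$A]]
  for (c in 1:4)
    expect_equal(tab$apoz[tab$unit == 1 & tab$channel == c],
                 mean(A[((c - 1) * P + 1):(c * P), ] == 0))
  # forcing a channel dead (or always-on) pins APoZ at the extremes
  dead <- model
  dead$layers[[u1$D]]$W[, 2] <- 0
  dead$layers[[u1$D]]$b[2] <- -1
  expect_equal(collect_activations(dead, X)$apoz[2], 1)
  alive <- model
  alive$layers[[u1$D]]$b[3] <- 50
  expect_equal(collect_activations(alive, X)$apoz[3], 0)
  # invariant to sample order
  perm <- sample(ncol(X))
  expect_equal(collect_activations(model, X[, perm])$apoz, tab$apoz)
  expect_error(collect_activations(model, X[, 0]), "empty")
})

test_that("ranking removes the largest-APoZ channels with floor and tie rules", {
  mk_tab <- function(apoz2) {
    tab <- data.frame(unit = rep(1:2, each = 8), channel = rep(1:8, 2),
                      apoz = c(seq(0, 0.7, 0.1), apoz2), n_samples = 10)
    class(tab) <- c("apoz_table", "data.frame")
    tab
  }
  tab <- mk_tab(c(0.9, 0.1, 0.8, 0.2, 0.3, 0.4, 0.5, 0.6))
  expect_equal(lengths(rank_and_select(tab, 0)$removals), c("1" = 0, "2" = 0))
  plan <- rank_and_select(tab, 0.25)   # floor(8 * 0.25) = 2 per unit
  expect_length(plan$removals[["2"]], 2)
  expect_setequal(plan$removals[["2"]], c(1, 3))  # the two largest APoZ
  expect_length(plan$removals[["1"]], 0)  # first unit never pruned
  # ordered by decreasing APoZ
  expect_equal(plan$removals[["2"]], c(1, 3))
  # equal APoZ everywhere: the highest-indexed channels are removed
  tie <- mk_tab(rep(0.5, 8))
  expect_equal(sort(rank_and_select(tie, 0.5)$removals[["2"]]), 5:8)
  expect_error(rank_and_select(tab, 1), "epsilon")
})

test_that("masking zeroes pruned channels and their producers exactly", {
  model <- build_sepnet(input_sp = c(10, 10), stem_channels = 8,
                        unit_channels = c(8, 4), seed = 11)
  set.seed(11)
  X <- matrix(rnorm(100 * 10), 100, 10)
  plan <- rank_and_select(collect_activations(model, X), 0.25)
  # empty plan leaves the model bitwise unchanged
  empty <- structure(list(epsilon = 0,
                          removals = list("1" = integer(0), "2" = integer(0))),
                     class = "pruning_plan")
  m0 <- mask_unit(model, empty)
  expect_identical(m0$layers, model$layers)
  masked <- mask_unit(model, plan)
  r <- plan$removals[["2"]]
  u <- model$meta$units[[2]]
  fwd <- nc$nn_forward(masked, X)
  P <- masked$layers[[u$D]]$geom$P
  for (j in r) {
    # the pruned channel's activation is identically zero for any input
    expect_true(all(fwd$acts[[u$A]][((j - 1) * P + 1):(j * P), ] == 0))
    expect_true(all(masked$layers[[u$D]]$W[, j] == 0))
    expect_true(all(masked$layers[[u$P]]$W[j, ] == 0))
    expect_true(all(masked$layers[[u$producer]]$W[, j] == 0))
  }
  # removal never touches the first unit
  expect_error(mask_unit(model, structure(list(epsilon = 0.25,
    removals = list("1" = 1L, "2" = integer(0))), class = "pruning_plan")),
    "first unit")
})

test_that("masked and materialized models are forward-equivalent", {
  res <- experiment_pruning_equivalence(n = 15, seed = 3)
  expect_equal(res$max_abs_diff, 0)
  expect_equal(res$max_cost_err, 0)
})

test_that("materialize shrinks parameters by exactly the planned amount", {
  model <- build_sepnet(input_sp = c(10, 10), stem_channels = 8,
                        unit_channels = c(8, 8), seed = 12)
  set.seed(12)
  X <- matrix(rnorm(100 * 8), 100, 8)
  plan <- rank_and_select(collect_activations(model, X), 0.25)
  masked <- mask_unit(model, plan)
  small <- materialize(masked)
  r <- length(plan$removals[["2"]])
  expect_equal(r, 2)
  u <- model$meta$units[[2]]
  K <- model$layers[[u$D]]$geom$K
  N <- model$layers[[u$P]]$c_out
  prod_in <- nrow(model$layers[[u$producer]]$W)
  expected_drop <- r * (K + 1) +      # depthwise filters + biases
    r * N +                           # pointwise input slices
    r * (prod_in + 1)                 # producer output filters + biases
  expect_equal(count_params(model) - count_params(small), expected_drop)
  # depthwise filter count drops 8 -> 6; unit output width is unchanged
  expect_equal(small$layers[[u$D]]$channels, 6)
  expect_equal(small$layers[[u$P]]$c_out, N)
  expect_equal(nrow(small$layers[[length(small$layers)]]$W),
               nrow(model$layers[[length(model$layers)]]$W))
  # out-of-sync masking is refused
  bad <- masked
  j <- plan$removals[["2"]][1]
  bad$layers[[u$D]]$W[1, j] <- 0.3
  expect_error(materialize(bad), "out of sync")
})

test_that("pruning schedules preserve accuracy within the expected margin", {
  g <- experiment_prune_finetune(0.25, "greedy", seed = 0, epochs = 20)
  expect_gte(g$acc_after, g$acc_before - 0.02)
  expect_lt(g$multadds_after, g$multadds_before)
  expect_lt(g$params_after, g$params_before)
  l <- experiment_prune_finetune(0.25, "layerwise", seed = 0, epochs = 20)
  expect_gte(l$acc_after, g$acc_after - 0.01)  # regression guard
  # epsilon = 0 is a no-op
  toy <- gen_toy_images(30, seed = 4)
  m <- build_sepnet(seed = 4)
  rep0 <- greedy_schedule(m, toy$X, toy$y, 0, train_config(epochs = 0))
  expect_identical(rep0$model$layers, m$layers)
  expect_equal(rep0$multadds_after, rep0$multadds_before)
})
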