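test_that("initial-volume trimming removes exactly the unstable prefix", {
  ts <- matrix(rnorm(52 * 140), 52, 140)
  expect_equal(ncol(trim_initial_volumes(ts)), 135)
  expect_identical(trim_initial_volumes(ts, 0), ts)
  expect_equal(trim_initial_volumes(ts, 5)[, 1], ts[, 6])
  expect_error(trim_initial_volumes(ts[, 1:5], 5), "5 timepoints")
  vol4 <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  expect_equal(dim(trim_initial_volumes(vol4, 5))[4], 5)
})

test_that("functional connectivity is textbook Pearson correlation", {
  t_ax <- seq_len(20)
  a <- sin(t_ax) + rnorm(20, 0, 0.1)
  ts <- rbind(a = a, b = 2 * a, c = -a)
  fc <- compute_fc(ts)
  expect_equal(unname(fc["a", "b"]), 1)
  expect_equal(unname(fc["a", "c"]), -1)
  expect_true(isSymmetric(unclass(fc)))
  expect_equal(unname(diag(fc)), rep(1, 3))
  a4 <- c(1, 2, 3, 4); b4 <- c(1, 3, 2, 4)
  fc4 <- compute_fc(rbind(a4, b4, c4 = c(4, 1, 1, 3)))
  expect_equal(unname(fc4[1, 2]), 0.8)  # = oracle below
  expect_equal(unname(fc4[1, 2]), oracle_pearson(a4, b4))
  expect_equal(unname(fc4[1, 3]), oracle_pearson(a4, c(4, 1, 1, 3)))
  bad <- rbind(x = rnorm(10), flat = rep(1, 10))
  expect_error(compute_fc(bad), "flat")
})

test_that("FC matrices from generated cohorts are well-formed", {
  coh <- gen_timeseries_cohort(cohort_spec(n_per_group = c(AD = 2, NC = 2),
                                           n_regions = 10, n_timepoints = 40,
                                           seed = 7))
  for (s in coh$subjects) {
    fc <- compute_fc(s$ts)
    expect_true(isSymmetric(unclass(fc)))
    expect_equal(unname(diag(fc)), rep(1, 10))
    expect_true(all(fc >= -1 & fc <= 1))
  }
})

test_that("fractional anisotropy follows the closed form and is scale-free", {
  expect_equal(fa_from_eigenvalues(c(1, 1, 1)), 0)
  expect_equal(fa_from_eigenvalues(c(1, 0, 0)), 1)
  expect_equal(fa_from_eigenvalues(c(3, 2, 1)), sqrt(3 / 14))
  expect_error(fa_from_eigenvalues(c(0, 0, 0)), "undefined")
  expect_error(fa_from_eigenvalues(c(-1, 1, 1)), "nonnegative")
  set.seed(11)
  for (r in 1:25) {
    e <- runif(3, 0, 5)
    fa <- fa_from_eigenvalues(e)
    expect_gte(fa, 0); expect_lte(fa, 1)
    for (c in c(0.1, 3)) expect_equal(fa_from_eigenvalues(c * e), fa)
  }
})

test_that("FCN thresholding keeps only supra-threshold positive edges", {
  fc <- matrix(c(1, .6, .2, .6, 1, .7, .2, .7, 1), 3, 3)
  full <- build_fcn(fc, 0)
  expect_equal(sum(full$weights > 0), 6)          # complete graph
  expect_equal(build_fcn(fc, 0.99)$n_nodes, 3)
  expect_equal(sum(build_fcn(fc, 0.99)$weights), 0)  # empty graph
  net <- build_fcn(fc, 0.5)
  expect_equal(sum(net$weights[upper.tri(net$weights)] > 0), 2)
  expect_equal(unname(net$weights[1, 2]), 0.6)
  expect_equal(unname(diag(net$weights)), rep(0, 3))
  # negative-edge policy: dropped by default, kept under absolute value
  fcn <- matrix(c(1, -.8, -.8, 1), 2, 2)
  expect_equal(sum(build_fcn(fcn, 0.3)$weights), 0)
  expect_equal(unname(build_fcn(fcn, 0.3, negative = "absolute")$weights[1, 2]),
               0.8)
  expect_error(build_fcn(fc, 1), "threshold")
})

test_that("DTISCN applies the inclusive FA threshold and absent entries", {
  fa <- matrix(0.19, 4, 4); diag(fa) <- 0
  expect_equal(sum(build_dtiscn(fa)$weights), 0)
  fa2 <- matrix(0.2, 4, 4); diag(fa2) <- 0
  expect_true(all(build_dtiscn(fa2)$weights[upper.tri(fa2)] == 0.2))
  # mixed 5x5: count supra-threshold present entries by enumeration
  set.seed(3)
  m <- matrix(runif(25, 0, 0.6), 5, 5)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m[1, 2] <- m[2, 1] <- NA
  diag(m) <- 0
  expected <- sum(m[upper.tri(m)] >= 0.2, na.rm = TRUE)
  net <- build_dtiscn(m)
  expect_equal(sum(net$weights[upper.tri(net$weights)] > 0), expected)
})

test_that("graph metrics are exact on canonical small graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  net <- neurocascade:::new_brain_network(tri, "FCN")
  expect_equal(node_degree(net), rep(2, 3))
  # neighbours of any triangle node form a connected unit-weight pair
  expect_equal(node_efficiency(net, 1), 1)
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  pnet <- neurocascade:::new_brain_network(path, "FCN")
  expect_equal(betweenness_centrality(pnet, 1), 0)
  expect_equal(betweenness_centrality(pnet, 2), 1)
  expect_equal(node_efficiency(pnet, 1), 0)  # single neighbour
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 0.5
  expect_equal(node_degree(neurocascade:::new_brain_network(iso, "FCN"), 3), 0)
  star <- matrix(0, 4, 4); star[1, 2:4] <- c(.3, .5, .9)
  star[2:4, 1] <- c(.3, .5, .9)
  expect_equal(node_degree(neurocascade:::new_brain_network(star, "FCN"), 1),
               1.7)
  for (n in 3:10) {
    kn <- matrix(1, n, n); diag(kn) <- 0
    expect_equal(node_degree(neurocascade:::new_brain_network(kn, "FCN")),
                 rep(n - 1, n))
  }
})

test_that("graph metrics agree with exhaustive path-enumeration oracles", {
  for (r in 1:20) {
    n <- sample(4:8, 1)
    w <- random_graph(n, seed = 400 + r)
    net <- neurocascade:::new_brain_network(w, "FCN")
    for (i in seq_len(n)) {
      expect_equal(node_degree(net, i), oracle_degree(w, i))
      expect_equal(node_efficiency(net, i), oracle_efficiency(w, i),
                   tolerance = 1e-8)
      expect_equal(betweenness_centrality(net, i), oracle_betweenness(w, i),
                   tolerance = 1e-8, info = sprintf("seed %d node %d", r, i))
    }
  }
})

test_that("feature extraction orders (network, metric, node) deterministically", {
  spec <- cohort_spec(n_per_group = c(AD = 1, NC = 1), seed = 2)
  ts <- gen_timeseries_cohort(spec)$subjects[[1]]$ts
  fa <- gen_fa_cohort(spec)$subjects[[1]]$fa
  fcn <- build_fcn(compute_fc(trim_initial_volumes(ts)), 0.3)
  dti <- build_dtiscn(fa)
  fv <- extract_features(list(fcn, dti))
  expect_length(fv, 312)  # 3 metrics x 52 nodes x 2 networks
  expect_true(all(is.finite(fv)))
  expect_length(extract_features(list(fcn)), 156)
  expect_match(names(fv)[1], "^FCN\\.degree\\.1$")
  expect_match(names(fv)[157], "^DTISCN\\.degree\\.1$")
  empty <- neurocascade:::new_brain_network(matrix(0, 52, 52), "FCN")
  expect_equal(unname(extract_features(list(empty))[1:52]), rep(0, 52))
  small <- neurocascade:::new_brain_network(matrix(0, 5, 5), "DTISCN")
  expect_error(extract_features(list(fcn, small)), "node count")
})

test_that("Welch t-test selection matches the closed-form oracle", {
  a <- matrix(c(1.1, 2.3, 0.7, 5, 6, 7), 3, 2)
  b <- matrix(c(2.0, 2.5, 3.1, 5.2, 5.9, 7.4), 3, 2)
  colnames(a) <- colnames(b) <- c("f1", "f2")
  sel <- ttest_select(a, b, alpha = 0.05)
  for (j in 1:2) {
    o <- oracle_welch(a[, j], b[, j])
    expect_equal(sel$t[j], unname(o["t"]), tolerance = 1e-10)
    expect_equal(sel$p[j], unname(o["p"]), tolerance = 1e-10)
  }
  expect_identical(sel$selected, sel$p < 0.05)
  expect_error(ttest_select(a[1, , drop = FALSE], b), "at least 2")
  # identical groups: nothing should look significant
  same <- matrix(rnorm(40), 10, 4)
  expect_equal(ttest_select(same, same)$t, rep(0, 4), tolerance = 1e-12)
  # BH correction is at least as conservative as none
  set.seed(9)
  x <- matrix(rnorm(200), 10); y <- matrix(rnorm(200), 10)
  expect_lte(sum(ttest_select(x, y, correction = "BH")$selected),
             sum(ttest_select(x, y)$selected))
})

test_that("planted group effects are recovered by t-test selection", {
  res <- experiment_selection_recovery(n_rep = 2, seed = 0)
  expect_true(all(res$recovered))
})
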