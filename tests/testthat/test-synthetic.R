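test_that("every generator is deterministic under its seed", {
  spec <- cohort_spec(n_per_group = c(AD = 3, NC = 3), n_regions = 12,
                      n_timepoints = 30, seed = 21)
  a <- gen_timeseries_cohort(spec); b <- gen_timeseries_cohort(spec)
  expect_identical(a, b)
  expect_identical(gen_fa_cohort(spec), gen_fa_cohort(spec))
  vs <- volume_spec(shape = c(12, 12, 10),
                    lesion_centers = list(mri = matrix(c(4, 4, 5), 1),
                                          pet = matrix(c(9, 9, 5), 1)),
                    lesion_radius = 2, seed = 21)
  expect_identical(gen_volume_cohort(vs, spec), gen_volume_cohort(vs, spec))
  # different seed, different data
  spec2 <- cohort_spec(n_per_group = c(AD = 3, NC = 3), n_regions = 12,
                       n_timepoints = 30, seed = 22)
  expect_false(identical(gen_timeseries_cohort(spec2), a))
})

test_that("cohorts are extensible without perturbing existing subjects", {
  small <- cohort_spec(n_per_group = c(AD = 2, NC = 2), n_regions = 10,
                       n_timepoints = 20, seed = 5)
  big <- cohort_spec(n_per_group = c(AD = 2, NC = 4), n_regions = 10,
                     n_timepoints = 20, seed = 5)
  a <- gen_timeseries_cohort(small); b <- gen_timeseries_cohort(big)
  # per-subject RNG streams: shared indices produce identical data
  expect_identical(a$subjects[[1]]$ts, b$subjects[[1]]$ts)
  expect_identical(a$subjects[[3]]$ts, b$subjects[[3]]$ts)
})

test_that("zero effect size produces group-exchangeable time series", {
  spec0 <- cohort_spec(n_per_group = c(AD = 1, NC = 1), n_regions = 20,
                       n_timepoints = 50, effect_size = 0, seed = 8)
  expect_identical(neurocascade:::.fc_template(spec0, "AD"),
                   neurocascade:::.fc_template(spec0, "NC"))
  spec1 <- cohort_spec(n_per_group = c(AD = 1, NC = 1), n_regions = 20,
                       n_timepoints = 50, effect_size = 1, seed = 8)
  tA <- neurocascade:::.fc_template(spec1, "AD")
  tN <- neurocascade:::.fc_template(spec1, "NC")
  expect_false(identical(tA, tN))
  # attenuation only touches entries incident to effect nodes
  off <- setdiff(seq_len(20), spec1$effect_nodes)
  expect_identical(tA[off, off], tN[off, off])
  expect_true(all(tA[spec1$effect_nodes, ] <= tN[spec1$effect_nodes, ]))
})

test_that("planted FC attenuation exceeds null-edge differences on average", {
  # Monte-Carlo: mean |FC difference| on effect edges vs untouched edges
  reps <- 10
  d_eff <- numeric(reps); d_null <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- cohort_spec(n_per_group = c(AD = 10, NC = 10), n_regions = 13,
                        n_timepoints = 80, effect_nodes = c(2, 7),
                        effect_size = 1, seed = 30 + r)
    coh <- gen_timeseries_cohort(spec)
    lab <- vapply(coh$subjects, `[[`, "", "label")
    fcs <- lapply(coh$subjects, function(s) compute_fc(s$ts))
    mfc <- function(g) Reduce(`+`, fcs[lab == g]) / sum(lab == g)
    dif <- mfc("NC") - mfc("AD")
    eff <- spec$effect_nodes
    others <- setdiff(seq_len(13), eff)
    d_eff[r] <- mean(dif[eff, others])
    d_null[r] <- mean(abs(dif[others, others][upper.tri(dif[others, others])]))
  }
  expect_gt(mean(d_eff), mean(d_null))
})

test_that("FA cohorts are symmetric, bounded, and carry the planted shift", {
  spec <- cohort_spec(n_per_group = c(AD = 30, NC = 30), n_regions = 20,
                      n_timepoints = 30, effect_nodes = c(3, 11),
                      effect_size = 1.5, seed = 40)
  coh <- gen_fa_cohort(spec)
  for (s in coh$subjects[c(1, 31)]) {
    expect_true(isSymmetric(s$fa))
    present <- !is.na(s$fa)
    expect_true(all(s$fa[present] >= 0 & s$fa[present] <= 1))
  }
  # absent fraction close to the configured rate (among backbone edges)
  fr <- mean(vapply(coh$subjects, function(s) {
    ut <- upper.tri(s$fa)
    tracked <- neurocascade:::.fa_backbone(spec) > 0
    mean(is.na(s$fa[ut & tracked]))
  }, 1))
  expect_equal(fr, spec$absent_frac, tolerance = 0.05)
  # FA-degree on the structural network recovers the shifted nodes
  lab <- vapply(coh$subjects, `[[`, "", "label")
  deg <- t(vapply(coh$subjects, function(s)
    node_degree(build_dtiscn(s$fa)), numeric(20)))
  sel <- ttest_select(deg[lab == "AD", ], deg[lab == "NC", ])
  expect_true(all(sel$selected[c(3, 11)]))
  # absent-fraction 1 gives an empty network after thresholding
  spec_all <- cohort_spec(n_per_group = c(AD = 1, NC = 1), n_regions = 10,
                          n_timepoints = 30, absent_frac = 1, seed = 41)
  fa1 <- gen_fa_cohort(spec_all)$subjects[[1]]$fa
  expect_equal(sum(build_dtiscn(fa1)$weights), 0)
})

test_that("volume pairs carry modality-specific class-dependent lesions", {
  vs <- volume_spec(seed = 3)
  spec <- cohort_spec(n_per_group = c(AD = 8, NC = 8), seed = 3)
  coh <- gen_volume_cohort(vs, spec)
  lab <- vapply(coh$subjects, `[[`, "", "label")
  mask_mri <- neurocascade:::.sphere_mask(vs$shape, vs$lesion_centers$mri[1, ],
                                          vs$lesion_radius)
  mask_pet <- neurocascade:::.sphere_mask(vs$shape, vs$lesion_centers$pet[1, ],
                                          vs$lesion_radius)
  stat <- function(s, mod, m) mean(s[[mod]][m]) - mean(s[[mod]][!m])
  mri_stat <- vapply(coh$subjects, stat, 1, mod = "mri", m = mask_mri)
  pet_stat <- vapply(coh$subjects, stat, 1, mod = "pet", m = mask_pet)
  expect_lt(mean(mri_stat[lab == "AD"]), mean(mri_stat[lab == "NC"]))
  expect_lt(mean(pet_stat[lab == "AD"]), mean(pet_stat[lab == "NC"]))
  # the MRI lesion is absent from the PET channel and vice versa
  cross <- vapply(coh$subjects, stat, 1, mod = "pet", m = mask_mri)
  expect_lt(abs(mean(cross[lab == "AD"]) - mean(cross[lab == "NC"])),
            abs(mean(pet_stat[lab == "AD"]) - mean(pet_stat[lab == "NC"])) / 2)
})

test_that("zero contrast yields label-independent volumes; zero noise separates", {
  spec <- cohort_spec(n_per_group = c(AD = 10, NC = 10), seed = 6)
  vs0 <- volume_spec(class_contrast = 0, seed = 6)
  coh0 <- gen_volume_cohort(vs0, spec)
  lab <- vapply(coh0$subjects, `[[`, "", "label")
  mask <- neurocascade:::.sphere_mask(vs0$shape, vs0$lesion_centers$mri[1, ],
                                      vs0$lesion_radius)
  s0 <- vapply(coh0$subjects, function(s) mean(s$mri[mask]) - mean(s$mri[!mask]), 1)
  expect_gt(t.test(s0[lab == "AD"], s0[lab == "NC"])$p.value, 0.01)
  vsn <- volume_spec(noise_sd = 0, seed = 6)
  cohn <- gen_volume_cohort(vsn, spec)
  sn <- vapply(cohn$subjects, function(s) mean(s$mri[mask]) - mean(s$mri[!mask]), 1)
  # noiseless lesion contrast separates the classes linearly
  expect_lt(max(sn[lab == "AD"]), min(sn[lab == "NC"]))
})

test_that("specs validate their invariants", {
  expect_error(cohort_spec(n_per_group = c(3, 3)), "named")
  expect_error(cohort_spec(n_per_group = c(AD = 2, NC = 2), n_regions = 2),
               "n_regions")
  expect_error(cohort_spec(n_per_group = c(AD = 2, NC = 2),
                           effect_nodes = c(1, 99)), "effect_nodes")
  expect_error(cohort_spec(n_per_group = c(AD = 2, NC = 2),
                           effect_size = -1), "effect_size")
  expect_error(volume_spec(shape = c(10, 10, 10),
                           lesion_centers = list(mri = matrix(c(1, 5, 5), 1),
                                                 pet = matrix(c(5, 5, 5), 1)),
                           lesion_radius = 3), "outside")
})
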