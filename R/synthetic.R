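# Synthetic cohort generators. These emulate the statistical structure
# the downstream analyses assume -- group-structured region time series
# with block covariance, FA matrices with group-shifted edges, and
# paired MRI/PET-like volumes with class-dependent focal lesions -- so
# that every pipeline stage is testable without any imaging download.
# Each subject draws from its own RNG stream derived from (seed, subject
# index), so cohorts are extensible without perturbing existing subjects.

.subject_seed <- function(seed, idx) {
  (as.numeric(seed) * 7919 + idx * 104729) %% 2147483647
}

#' Cohort specification
#'
#' Describes a labeled synthetic cohort. Group differences are planted
#' at `effect_nodes`: functional correlations incident to those nodes
#' are attenuated and FA edges shifted in the affected groups (AD fully,
#' MCI at half strength). Effect magnitudes are artifact parameters, not
#' literature values.
#'
#' @param n_per_group Named counts per label, names among `AD`, `MCI`,
#'   `NC`.
#' @param n_regions Number of brain regions (default 52).
#' @param n_timepoints BOLD series length before trimming (default 140).
#' @param effect_nodes 1-based node indices carrying group differences;
#'   by default four nodes spread across the parcellation (5, 12, 23,
#'   40 at 52 regions).
#' @param effect_size Standardized effect magnitude (>= 0); 0 plants no
#'   difference.
#' @param noise_sd Residual noise scale.
#' @param absent_frac Fraction of FA entries marked absent (fiber
#'   tracking failure), per subject.
#' @param seed RNG seed; identical seed gives an identical cohort.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(AD = 30, NC = 30), n_regions = 52,
                        n_timepoints = 140, effect_nodes = NULL,
                        effect_size = 1, noise_sd = 0.2,
                        absent_frac = 0.15, seed = 1) {
  if (is.null(effect_nodes))
    effect_nodes <- unique(pmax(1, round(n_regions * c(0.1, 0.23, 0.44, 0.77))))
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("AD", "MCI", "NC")))
    stop("cohort_spec: n_per_group must be named with labels among AD, MCI, NC")
  if (n_regions < 3) stop("cohort_spec: n_regions must be >= 3")
  if (length(effect_nodes) &&
      (any(effect_nodes < 1) || any(effect_nodes > n_regions)))
    stop("cohort_spec: effect_nodes out of range 1..n_regions")
  if (effect_size < 0) stop("cohort_spec: effect_size must be >= 0")
  if (absent_frac < 0 || absent_frac > 1)
    stop("cohort_spec: absent_frac must lie in [0, 1]")
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 n_timepoints = n_timepoints,
                 effect_nodes = as.integer(effect_nodes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 absent_frac = absent_frac, seed = seed),
            class = "cohort_spec")
}

.cohort_labels <- function(spec) {
  rep(names(spec$n_per_group), times = spec$n_per_group)
}

# block-community correlation template; AD/MCI groups attenuate the
# within-block correlations incident to effect nodes
.fc_template <- function(spec, group) {
  n <- spec$n_regions
  n_blocks <- max(2, round(n / 13))
  block <- sort(rep(seq_len(n_blocks), length.out = n))
  R <- matrix(0.1, n, n)
  same <- outer(block, block, `==`)
  R[same] <- 0.5
  atten <- switch(group, AD = 1, MCI = 0.5, NC = 0) *
    min(0.2 * spec$effect_size, 0.9)
  if (atten > 0 && length(spec$effect_nodes)) {
    for (v in spec$effect_nodes) {
      peers <- which(block == block[v])
      R[v, peers] <- R[v, peers] * (1 - atten)
      R[peers, v] <- R[v, peers]
    }
  }
  diag(R) <- 1
  R
}

#' Generate a cohort of region-level BOLD time series
#'
#' Each subject's `regions x timepoints` matrix is drawn from a
#' multivariate normal whose correlation template has block-community
#' structure; in affected groups the correlations incident to
#' `effect_nodes` are attenuated. Additive white measurement noise of
#' scale `noise_sd` is superimposed. Non-effect structure is identical
#' across groups.
#'
#' @param spec A [cohort_spec()].
#' @return A `ts_cohort`: list with `$subjects` (each `id`, `label`,
#'   `ts`) and `$spec`.
#' @export
gen_timeseries_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- .cohort_labels(spec)
  groups <- unique(labels)
  chols <- lapply(groups, function(g) {
    R <- .fc_template(spec, g)
    L <- tryCatch(chol(R), error = function(e)
      stop("gen_timeseries_cohort: requested correlation template for group ",
           g, " is not positive definite (", conditionMessage(e), ")"))
    L
  })
  names(chols) <- groups
  region_labels <- sprintf("region_%02d", seq_len(spec$n_regions))
  subjects <- lapply(seq_along(labels), function(i) {
    set.seed(.subject_seed(spec$seed, i))
    Z <- matrix(stats::rnorm(spec$n_regions * spec$n_timepoints),
                spec$n_regions, spec$n_timepoints)
    ts <- crossprod(chols[[labels[i]]], Z) +
      spec$noise_sd * matrix(stats::rnorm(length(Z)), nrow(Z), ncol(Z))
    rownames(ts) <- region_labels
    list(id = sprintf("sub-%03d", i), label = labels[i], ts = ts)
  })
  structure(list(subjects = subjects, spec = spec), class = "ts_cohort")
}

# sparse structural backbone shared by all subjects (seeded by spec)
.fa_backbone <- function(spec) {
  set.seed(.subject_seed(spec$seed, 0))
  n <- spec$n_regions
  A <- matrix(0, n, n)
  for (d in 1:3) {  # banded neighbours give a connected backbone
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    A[idx] <- 1
  }
  extra <- which(upper.tri(A) & A == 0)
  extra <- sample(extra, round(0.08 * length(extra)))
  A[extra] <- 1
  A <- A + t(A); A[A > 0] <- 1
  T0 <- matrix(0, n, n)
  T0[A > 0] <- stats::runif(sum(A > 0), 0.3, 0.7)
  T0[lower.tri(T0)] <- t(T0)[lower.tri(T0)]
  T0
}

#' Generate a cohort of regional fractional-anisotropy matrices
#'
#' Subjects share a sparse structural backbone of baseline FA values in
#' `[0.3, 0.7]`; in affected groups the edges incident to
#' `effect_nodes` are shifted downward by `fa_shift` (AD fully, MCI at
#' half strength). A fraction `absent_frac` of present edges is marked
#' absent (`NA`) per subject, emulating fiber-tracking failure.
#'
#' @param spec A [cohort_spec()].
#' @param fa_shift Group FA shift on effect edges (default
#'   `0.1 * spec$effect_size`).
#' @return An `fa_cohort`: list with `$subjects` (each `id`, `label`,
#'   `fa`) and `$spec`.
#' @export
gen_fa_cohort <- function(spec, fa_shift = 0.1 * spec$effect_size) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- .cohort_labels(spec)
  T0 <- .fa_backbone(spec)
  n <- spec$n_regions
  region_labels <- sprintf("region_%02d", seq_len(n))
  present0 <- T0 > 0
  subjects <- lapply(seq_along(labels), function(i) {
    set.seed(.subject_seed(spec$seed, i) + 1)
    shift <- switch(labels[i], AD = 1, MCI = 0.5, NC = 0) * fa_shift
    Tg <- T0
    if (shift != 0 && length(spec$effect_nodes)) {
      for (v in spec$effect_nodes) {
        Tg[v, ] <- pmax(Tg[v, ] - shift * (Tg[v, ] > 0), 0.01 * (Tg[v, ] > 0))
        Tg[, v] <- Tg[v, ]
      }
    }
    noise <- matrix(stats::rnorm(n * n, 0, 0.15 * spec$noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    fa <- pmin(pmax(Tg + noise * (Tg > 0), 0), 1)
    if (spec$absent_frac > 0) {
      cand <- which(upper.tri(fa) & present0)
      drop <- sample(cand, round(spec$absent_frac * length(cand)))
      fa[drop] <- NA
      fa <- t(fa); fa[drop] <- NA; fa <- t(fa)
    }
    fa[!present0] <- NA  # never-tracked pairs are absent, not zero
    diag(fa) <- 0
    dimnames(fa) <- list(region_labels, region_labels)
    list(id = sprintf("sub-%03d", i), label = labels[i], fa = fa)
  })
  structure(list(subjects = subjects, spec = spec), class = "fa_cohort")
}

#' Volume specification
#'
#' Geometry of the synthetic MRI/PET-like volume pairs. The default
#' shape 25 x 21 x 20 is the full 100 x 81 x 80 enclosing box scaled
#' down by 4 to keep desk-scale training fast; the full size remains
#' available by configuration. Lesion centers are given separately per
#' modality so that each modality carries an independent share of the
#' class signal and multimodal fusion is informative.
#'
#' @param shape 3D voxel dimensions.
#' @param lesion_centers List with `mri` and `pet` matrices of lesion
#'   center voxel coordinates (rows = lesions, 1-based).
#' @param lesion_radius Lesion radius in voxels.
#' @param class_contrast Intensity reduction inside lesions for AD (MCI
#'   gets half).
#' @param noise_sd Additive voxel noise scale.
#' @param seed RNG seed for the shared background.
#' @return A `volume_spec`.
#' @export
volume_spec <- function(shape = c(25, 21, 20),
                        lesion_centers = list(mri = matrix(c(8, 7, 10), 1),
                                              pet = matrix(c(18, 14, 10), 1)),
                        lesion_radius = 3.5, class_contrast = 0.5,
                        noise_sd = 0.6, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4))
  for (mod in c("mri", "pet")) {
    cc <- lesion_centers[[mod]]
    if (is.null(cc)) stop("volume_spec: lesion_centers needs mri and pet")
    if (any(t(cc) - lesion_radius < 1) || any(t(cc) + lesion_radius > shape))
      stop("volume_spec: ", mod, " lesion sphere extends outside the volume")
  }
  structure(list(shape = as.integer(shape), lesion_centers = lesion_centers,
                 lesion_radius = lesion_radius,
                 class_contrast = class_contrast, noise_sd = noise_sd,
                 seed = seed),
            class = "volume_spec")
}

.sphere_mask <- function(shape, center, radius) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, shape)
}

.background_volume <- function(shape) {
  c0 <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- ((g$x - c0[1]) / (0.45 * shape[1]))^2 +
    ((g$y - c0[2]) / (0.45 * shape[2]))^2 +
    ((g$z - c0[3]) / (0.45 * shape[3]))^2
  array(2 * exp(-r2 / 2), shape)  # smooth head-like bump
}

#' Generate a cohort of paired MRI/PET-like volumes
#'
#' Per subject: a shared smooth background, class-dependent focal
#' lesions (intensity reduced by `class_contrast` in AD, half in MCI,
#' none in NC; MRI and PET lesions at independent sites), a subject
#' gain factor, and i.i.d. voxel noise. With `class_contrast = 0` the
#' class label is independent of the data by construction.
#'
#' @param vspec A [volume_spec()].
#' @param cspec A [cohort_spec()] (labels, counts, seed).
#' @return A `volume_cohort`: list with `$subjects` (each `id`, `label`,
#'   `mri`, `pet`), `$vspec`, `$cspec`.
#' @export
gen_volume_cohort <- function(vspec, cspec) {
  stopifnot(inherits(vspec, "volume_spec"), inherits(cspec, "cohort_spec"))
  labels <- .cohort_labels(cspec)
  bg <- .background_volume(vspec$shape)
  masks <- lapply(c(mri = "mri", pet = "pet"), function(mod) {
    cc <- vspec$lesion_centers[[mod]]
    m <- array(FALSE, vspec$shape)
    for (r in seq_len(nrow(cc)))
      m <- m | .sphere_mask(vspec$shape, cc[r, ], vspec$lesion_radius)
    m
  })
  subjects <- lapply(seq_along(labels), function(i) {
    set.seed(.subject_seed(vspec$seed * 131 + cspec$seed, i))
    severity <- switch(labels[i], AD = 1, MCI = 0.5, NC = 0)
    gain <- stats::rnorm(1, 1, 0.05)
    one <- function(mod) {
      v <- bg - severity * vspec$class_contrast * masks[[mod]]
      gain * v + vspec$noise_sd *
        array(stats::rnorm(prod(vspec$shape)), vspec$shape)
    }
    list(id = sprintf("sub-%03d", i), label = labels[i],
         mri = one("mri"), pet = one("pet"))
  })
  structure(list(subjects = subjects, vspec = vspec, cspec = cspec),
            class = "volume_cohort")
}
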