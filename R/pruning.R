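# APoZ-based channel pruning of depthwise-separable units.
#
# A separable unit is the triple <L_i, D_i, P_i>: input activations L_i,
# a depthwise 3x3 stage D_i (one spatial filter per channel, ReLU after),
# and a pointwise 1x1 stage P_i. Channel j of the post-ReLU depthwise
# activation corresponds one-to-one to input channel j of the unit, so
# removing it removes the j-th depthwise filter, the j-th input slice of
# every P_i filter, and the j-th output filter of P_{i-1} (the producer
# of L_i). Pruning never changes a unit's output dimension N.

#' Build a depthwise-separable toy network
#'
#' A standard-convolution stem followed by depthwise-separable units and
#' a global-average-pool + fully-connected softmax head. The stem plays
#' the producer role for the first unit's input; the first unit's
#' channels are nevertheless never pruned.
#'
#' @param input_sp Spatial input size (2D vector).
#' @param c_in Input channels (default 1).
#' @param stem_channels Channels produced by the 3x3 stem.
#' @param unit_channels Output channels of each separable unit, in
#'   order; the first unit consumes `stem_channels`.
#' @param classes Output classes.
#' @param seed Xavier initialization seed.
#' @return An initialized `nn_model` whose `meta$units` records, per
#'   unit, the indices of its depthwise layer, post-depthwise ReLU,
#'   pointwise layer, producer layer, and channel count.
#' @export
build_sepnet <- function(input_sp = c(12, 12), c_in = 1, stem_channels = 8,
                         unit_channels = c(8, 8), classes = 2, seed = 1) {
  layers <- list(nn_conv(input_sp, c_in, stem_channels, k = 3))
  sp <- layers[[1]]$geom$out_sp
  layers <- c(layers, list(nn_relu(prod(sp) * stem_channels)))
  units <- list()
  prev_idx <- 1
  ch <- stem_channels
  for (u in seq_along(unit_channels)) {
    dw <- nn_depthwise(sp, ch, k = 3)
    sp_out <- dw$geom$out_sp
    i0 <- length(layers)
    layers <- c(layers, list(
      dw,
      nn_relu(prod(sp_out) * ch),
      nn_pointwise(prod(sp_out), ch, unit_channels[u]),
      nn_relu(prod(sp_out) * unit_channels[u])))
    units[[u]] <- list(D = i0 + 1, A = i0 + 2, P = i0 + 3,
                       producer = prev_idx, channels = ch)
    prev_idx <- i0 + 3
    sp <- sp_out
    ch <- unit_channels[u]
  }
  layers <- c(layers, list(nn_gap(prod(sp), ch), nn_fc(ch, classes)))
  m <- nn_model(layers, meta = list(units = units, input_sp = input_sp,
                                    c_in = c_in, classes = classes))
  nn_init_xavier(m, seed = seed)
}

#' Average percentage of zeros per depthwise channel
#'
#' Runs the evaluation set through the model and, for every separable
#' unit and channel, records the mean fraction of exactly-zero
#' activations in the post-ReLU depthwise feature map (over samples and
#' spatial positions). ReLU emits exact zeros, so zero detection is
#' exact equality. High APoZ marks unimportant channels. The statistic
#' is invariant to the ordering of the evaluation samples.
#'
#' @param model A [build_sepnet()] model.
#' @param X Evaluation inputs, `features x samples` matrix.
#' @return An `apoz_table` data frame: `unit`, `channel`, `apoz`,
#'   `n_samples`.
#' @export
collect_activations <- function(model, X) {
  if (is.null(dim(X)) || ncol(X) == 0)
    stop("collect_activations: empty evaluation set")
  units <- model$meta$units
  if (is.null(units)) stop("collect_activations: model has no separable units")
  fwd <- nn_forward(model, X)
  out <- do.call(rbind, lapply(seq_along(units), function(u) {
    ui <- units[[u]]
    A <- fwd$acts[[ui$A]]                       # (P * channels) x B
    P <- model$layers[[ui$D]]$geom$P
    apoz <- vapply(seq_len(ui$channels), function(c)
      mean(A[((c - 1) * P + 1):(c * P), , drop = FALSE] == 0), numeric(1))
    data.frame(unit = u, channel = seq_len(ui$channels), apoz = apoz,
               n_samples = ncol(X))
  }))
  class(out) <- c("apoz_table", "data.frame")
  out
}

#' Rank channels by APoZ and select removals
#'
#' Per unit, channels are sorted by APoZ from small to large and the
#' `floor(M * epsilon)` channels with the largest APoZ are marked for
#' removal; on ties the lower channel index is retained (the
#' higher-indexed channel is removed). The first unit's input channels
#' are never removed.
#'
#' @param apoz An [collect_activations()] table.
#' @param epsilon Pruning ratio in `[0, 1)`, scalar or one value per
#'   unit.
#' @return A `pruning_plan`: list with `epsilon` and `removals` (one
#'   integer vector per unit, ordered by decreasing APoZ).
#' @export
rank_and_select <- function(apoz, epsilon) {
  stopifnot(inherits(apoz, "apoz_table"))
  units <- sort(unique(apoz$unit))
  eps <- rep_len(epsilon, length(units))
  if (any(eps < 0 | eps >= 1))
    stop("rank_and_select: epsilon must lie in [0, 1)")
  removals <- lapply(units, function(u) {
    if (u == 1) return(integer(0))  # first unit's input channels are kept
    tab <- apoz[apoz$unit == u, ]
    M <- nrow(tab)
    m_rm <- floor(M * eps[u])
    if (m_rm >= M)
      stop("rank_and_select: epsilon would empty unit ", u)
    if (m_rm == 0) return(integer(0))
    ord <- order(tab$apoz, tab$channel)  # ascending; ties keep low index
    rev(tab$channel[ord[(M - m_rm + 1):M]])
  })
  names(removals) <- as.character(units)
  structure(list(epsilon = eps, removals = removals),
            class = "pruning_plan")
}

.check_plan <- function(model, plan) {
  units <- model$meta$units
  if (is.null(units)) stop("model has no separable units")
  if (length(plan$removals) != length(units))
    stop("pruning plan covers ", length(plan$removals),
         " units but the model has ", length(units))
  for (u in seq_along(units)) {
    r <- plan$removals[[u]]
    if (length(r) && (any(r < 1) || any(r > units[[u]]$channels)))
      stop("pruning plan: unit ", u, " removal indices out of range")
    if (u == 1 && length(r))
      stop("pruning plan: first unit's input channels cannot be removed")
  }
  invisible(TRUE)
}

# 1-masks matching every parameter, with zeros at pruned slots
.plan_masks <- function(model, plan) {
  masks <- lapply(model$layers, function(l)
    if (is.null(l$W)) NULL else list(W = l$W * 0 + 1, b = l$b * 0 + 1))
  units <- model$meta$units
  for (u in seq_along(units)) {
    r <- plan$removals[[u]]
    if (!length(r)) next
    ui <- units[[u]]
    masks[[ui$D]]$W[, r] <- 0
    masks[[ui$D]]$b[r] <- 0
    masks[[ui$P]]$W[r, ] <- 0
    masks[[ui$producer]]$W[, r] <- 0  # conv stem or pointwise: column = output filter
    masks[[ui$producer]]$b[r] <- 0
  }
  masks
}

#' Mask pruned channels in place
#'
#' Sets to zero every weight belonging to a removed channel -- the
#' depthwise filter and bias, the matching input slice of the unit's
#' pointwise filters, and the producing output filter (and bias) of the
#' previous unit's pointwise stage (or the stem) -- and records a
#' gradient mask so those entries receive no updates during
#' fine-tuning. The masked network computes exactly what the
#' materialized smaller network computes.
#'
#' @param model A [build_sepnet()] model.
#' @param plan A [rank_and_select()] plan.
#' @return The masked model; `meta$masks` holds the gradient masks and
#'   `meta$plan` the plan.
#' @export
mask_unit <- function(model, plan) {
  .check_plan(model, plan)
  masks <- .plan_masks(model, plan)
  for (i in seq_along(model$layers)) {
    if (is.null(masks[[i]])) next
    model$layers[[i]]$W <- model$layers[[i]]$W * masks[[i]]$W
    model$layers[[i]]$b <- model$layers[[i]]$b * masks[[i]]$b
  }
  model$meta$masks <- masks
  model$meta$plan <- plan
  model
}

#' Materialize a masked model into a smaller architecture
#'
#' Physically removes the zeroed filters and slices planned by
#' [mask_unit()]. Errors if any to-be-removed slot holds a nonzero
#' weight (mask and materialize out of sync). Output dimensionality of
#' every unit is preserved; the parameter count decreases by exactly
#' the planned amount.
#'
#' @param model A masked model.
#' @param plan The plan used for masking (defaults to the recorded one).
#' @return A smaller `nn_model`, forward-equivalent to the masked model.
#' @export
materialize <- function(model, plan = model$meta$plan) {
  if (is.null(plan)) stop("materialize: no pruning plan recorded or supplied")
  .check_plan(model, plan)
  units <- model$meta$units
  for (u in seq_along(units)) {
    r <- plan$removals[[u]]
    if (!length(r)) next
    ui <- units[[u]]
    slots <- c(model$layers[[ui$D]]$W[, r], model$layers[[ui$D]]$b[r],
               model$layers[[ui$P]]$W[r, ],
               model$layers[[ui$producer]]$W[, r],
               model$layers[[ui$producer]]$b[r])
    if (any(slots != 0))
      stop("materialize: unit ", u,
           " has nonzero weights in pruned slots; mask and materialize out of sync")
  }
  for (u in seq_along(units)) {
    r <- plan$removals[[u]]
    if (!length(r)) next
    ui <- units[[u]]
    keep <- setdiff(seq_len(units[[u]]$channels), r)
    pr <- model$layers[[ui$producer]]
    pr$W <- pr$W[, keep, drop = FALSE]
    pr$b <- pr$b[keep]
    if (pr$type == "conv") pr$c_out <- length(keep)
    if (pr$type == "pointwise") pr$c_out <- length(keep)
    pr$out_dim <- if (pr$type == "conv") pr$geom$P * pr$c_out
                  else pr$P * pr$c_out
    model$layers[[ui$producer]] <- pr
    model$layers[[ui$producer + 1]]$in_dim <- pr$out_dim  # its ReLU
    model$layers[[ui$producer + 1]]$out_dim <- pr$out_dim
    dw <- model$layers[[ui$D]]
    dw$W <- dw$W[, keep, drop = FALSE]
    dw$b <- dw$b[keep]
    dw$channels <- length(keep)
    dw$in_dim <- dw$geom$S * dw$channels
    dw$out_dim <- dw$geom$P * dw$channels
    model$layers[[ui$D]] <- dw
    model$layers[[ui$A]]$in_dim <- dw$out_dim
    model$layers[[ui$A]]$out_dim <- dw$out_dim
    pw <- model$layers[[ui$P]]
    pw$W <- pw$W[keep, , drop = FALSE]
    pw$c_in <- length(keep)
    pw$in_dim <- pw$P * pw$c_in
    model$layers[[ui$P]] <- pw
    model$meta$units[[u]]$channels <- length(keep)
  }
  model$meta$masks <- NULL
  model$meta$plan <- NULL
  nn_model(model$layers, model$meta)
}

#' Parameter count of a model
#' @param model An `nn_model`.
#' @return Total number of weights and biases.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l)
    if (is.null(l$W)) 0 else length(l$W) + length(l$b), numeric(1)))
}

#' Multiply-accumulate count of a model's forward pass
#'
#' Counts one multiply-add per kernel weight per output position
#' (biases and activations excluded), the same granularity as the
#' closed-form layer accounting.
#'
#' @param model An `nn_model`.
#' @param by_layer Return the per-layer vector instead of the total.
#' @return Mult-add count(s).
#' @export
model_multadds <- function(model, by_layer = FALSE) {
  ma <- vapply(model$layers, function(l) switch(l$type,
    conv = l$geom$P * l$geom$KC * l$c_out,
    depthwise = l$geom$P * l$geom$K * l$channels,
    pointwise = l$P * l$c_in * l$c_out,
    fc = nrow(l$W) * ncol(l$W),
    0), numeric(1))
  if (by_layer) ma else sum(ma)
}

# internal: split off a held-out APoZ evaluation set, prune, finetune
.prune_report <- function(model, before, after, plan, apoz) {
  list(model = after, plan = plan, apoz = apoz,
       params_before = count_params(before),
       params_after = count_params(after),
       multadds_before = model_multadds(before),
       multadds_after = model_multadds(after))
}

#' One-shot (greedy) pruning schedule
#'
#' Prunes all units at once: collect APoZ on a held-out evaluation
#' split of the training data, rank and select with ratio `epsilon`,
#' mask, fine-tune the surviving weights, then materialize. With
#' `epsilon = 0` the model is returned unchanged and fine-tuning is
#' skipped.
#'
#' @param model A [build_sepnet()] model (typically already trained).
#' @param X,y Training inputs and integer labels (1-based).
#' @param epsilon Pruning ratio.
#' @param cfg A [train_config()] for fine-tuning.
#' @param eval_frac Fraction of the data held out for APoZ collection.
#' @return A report list: pruned `model`, `plan`, `apoz`, parameter and
#'   mult-add counts before/after.
#' @export
greedy_schedule <- function(model, X, y, epsilon, cfg = train_config(),
                            eval_frac = 0.2) {
  before <- model
  set.seed(cfg$seed)
  n_eval <- max(1, round(eval_frac * ncol(X)))
  ev <- sample.int(ncol(X), n_eval)
  apoz <- collect_activations(model, X[, ev, drop = FALSE])
  plan <- rank_and_select(apoz, epsilon)
  if (all(lengths(plan$removals) == 0))
    return(.prune_report(model, before, model, plan, apoz))
  masked <- mask_unit(model, plan)
  if (cfg$epochs > 0)
    masked <- nn_train(masked, X[, -ev, drop = FALSE], y[-ev], cfg,
                       masks = masked$meta$masks)
  small <- materialize(masked, plan)
  .prune_report(model, before, small, plan, apoz)
}

#' Layer-by-layer pruning schedule
#'
#' Prunes units from shallow to deep, re-collecting APoZ and
#' fine-tuning after each unit, then materializes once at the end.
#'
#' @inheritParams greedy_schedule
#' @return Same report structure as [greedy_schedule()].
#' @export
layerwise_schedule <- function(model, X, y, epsilon, cfg = train_config(),
                               eval_frac = 0.2) {
  before <- model
  set.seed(cfg$seed)
  n_eval <- max(1, round(eval_frac * ncol(X)))
  ev <- sample.int(ncol(X), n_eval)
  units <- model$meta$units
  eps <- rep_len(epsilon, length(units))
  cum <- lapply(units, function(u) integer(0))
  names(cum) <- as.character(seq_along(units))
  apoz <- NULL
  for (u in seq_along(units)) {
    if (u == 1 || eps[u] == 0) next
    apoz <- collect_activations(model, X[, ev, drop = FALSE])
    eps_u <- ifelse(seq_along(units) == u, eps, 0)
    plan_u <- rank_and_select(apoz, eps_u)
    cum[[as.character(u)]] <- plan_u$removals[[as.character(u)]]
    plan_cum <- structure(list(epsilon = eps, removals = cum),
                          class = "pruning_plan")
    model <- mask_unit(model, plan_cum)
    if (cfg$epochs > 0)
      model <- nn_train(model, X[, -ev, drop = FALSE], y[-ev], cfg,
                        masks = model$meta$masks)
  }
  plan_cum <- structure(list(epsilon = eps, removals = cum),
                        class = "pruning_plan")
  if (all(lengths(cum) == 0))
    return(.prune_report(model, before, model, plan_cum, apoz))
  small <- materialize(model, plan_cum)
  .prune_report(model, before, small, plan_cum, apoz)
}
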