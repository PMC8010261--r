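#' Layer cost specification
#'
#' Describes a single convolution layer for closed-form cost accounting:
#' a square `d1 x d1` feature map with `m` input channels mapped to `n`
#' output channels by a `d2 x d2` kernel.
#'
#' @param d1 Feature-map width/height (positive integer).
#' @param d2 Kernel width/height (positive integer).
#' @param m Input channel count.
#' @param n Output channel count.
#' @return An object of class `layer_cost_spec`.
#' @export
#' @examples
#' layer_cost_spec(32, 3, 16, 32)
layer_cost_spec <- function(d1, d2, m, n) {
  vals <- c(d1 = d1, d2 = d2, m = m, n = n)
  if (any(!is.finite(vals)) || any(vals < 1) || any(vals != round(vals)))
    stop("layer_cost_spec: d1, d2, m, n must all be positive integers")
  structure(list(d1 = as.numeric(d1), d2 = as.numeric(d2),
                 m = as.numeric(m), n = as.numeric(n)),
            class = "layer_cost_spec")
}

#' Multiply-accumulate count of a standard convolution layer
#'
#' A standard convolution over a `d1 x d1 x m` input with a
#' `d2 x d2 x m x n` kernel costs `d1^2 * d2^2 * m * n` multiply-adds
#' (bias additions and activations are excluded at this granularity).
#'
#' @param spec A [layer_cost_spec()].
#' @return Multiply-add count (numeric, exact for integer inputs).
#' @export
#' @examples
#' conv_cost(layer_cost_spec(32, 3, 16, 32))
conv_cost <- function(spec) {
  stopifnot(inherits(spec, "layer_cost_spec"))
  spec$d1^2 * spec$d2^2 * spec$m * spec$n
}

#' Parameter count of a standard convolution layer
#'
#' `d2^2 * m * n` weights; independent of the feature-map size `d1`.
#'
#' @inheritParams conv_cost
#' @return Parameter count.
#' @export
conv_params <- function(spec) {
  stopifnot(inherits(spec, "layer_cost_spec"))
  spec$d2^2 * spec$m * spec$n
}

#' Multiply-accumulate count of a depthwise-separable unit
#'
#' Factorizes the standard convolution into a depthwise spatial stage
#' (`d1^2 * d2^2 * m`) followed by a pointwise 1x1 stage
#' (`m * n * d1^2`). The ratio to [conv_cost()] is `1/n + 1/d2^2`.
#'
#' @inheritParams conv_cost
#' @return Multiply-add count.
#' @export
separable_cost <- function(spec) {
  stopifnot(inherits(spec, "layer_cost_spec"))
  spec$d1^2 * spec$d2^2 * spec$m + spec$m * spec$n * spec$d1^2
}

#' Multiply-accumulate count of a channel-pruned separable unit
#'
#' Removing a fraction `epsilon` of the unit's `m` channels scales both
#' the depthwise and the pointwise term by `(1 - epsilon)`; the output
#' dimension `n` is unchanged.
#'
#' @inheritParams conv_cost
#' @param epsilon Pruning ratio, in `[0, 1)`.
#' @return Multiply-add count after pruning.
#' @export
pruned_separable_cost <- function(spec, epsilon) {
  stopifnot(inherits(spec, "layer_cost_spec"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      is.na(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("pruned_separable_cost: epsilon must be a single value in [0, 1)")
  (1 - epsilon) * separable_cost(spec)
}

#' Network schedule constructor
#'
#' An ordered table of layers for ledger accounting. Spatial sizes chain
#' with ceiling division by stride ("same" padding convention, the one
#' under which the published MobileNet mult-add shares are quoted).
#'
#' @param kind Character vector: `"standard"`, `"depthwise"`,
#'   `"pointwise"` or `"fc"`.
#' @param d_in Input spatial size per layer (square maps; 1 for fc).
#' @param k Kernel size per layer (1 for pointwise/fc).
#' @param c_in,c_out Channel (or unit) counts per layer.
#' @param stride Stride per layer.
#' @return A `network_schedule` data frame.
#' @export
network_schedule <- function(kind, d_in, k, c_in, c_out, stride = 1) {
  n <- length(kind)
  sched <- data.frame(kind = as.character(kind), d_in = as.numeric(d_in),
                      k = as.numeric(k), c_in = as.numeric(c_in),
                      c_out = as.numeric(c_out),
                      stride = as.numeric(rep_len(stride, n)),
                      stringsAsFactors = FALSE)
  bad <- !sched$kind %in% c("standard", "depthwise", "pointwise", "fc")
  if (any(bad)) stop("network_schedule: unknown layer kind: ",
                     paste(unique(sched$kind[bad]), collapse = ", "))
  dw <- sched$kind == "depthwise"
  if (any(dw & sched$c_in != sched$c_out))
    stop("network_schedule: depthwise layers must have c_in == c_out")
  # chain consistency: output spatial size and channels feed the next layer
  d_out <- ceiling(sched$d_in / sched$stride)
  for (i in seq_len(n - 1)) {
    conv_next <- sched$kind[i + 1] != "fc"
    if (sched$c_in[i + 1] != sched$c_out[i] && conv_next)
      stop(sprintf("network_schedule: channel mismatch between layers %d and %d (%g -> %g)",
                   i, i + 1, sched$c_out[i], sched$c_in[i + 1]))
    if (conv_next && sched$d_in[i + 1] != d_out[i])
      stop(sprintf("network_schedule: spatial mismatch between layers %d and %d (%g -> %g)",
                   i, i + 1, d_out[i], sched$d_in[i + 1]))
  }
  sched$d_out <- d_out
  class(sched) <- c("network_schedule", "data.frame")
  sched
}

#' Per-layer and total cost/parameter ledger
#'
#' Multiply-add counts use the output spatial grid (`d_out^2`) so that
#' strided layers are priced at the positions they actually compute;
#' depthwise layers cost `d_out^2 * k^2 * c`, pointwise `d_out^2 * c_in
#' * c_out`, fully-connected `c_in * c_out`.
#'
#' @param sched A [network_schedule()].
#' @return A data frame with per-layer `multadds`, `params`, and the
#'   attribute `totals` (list with totals and per-kind fractions).
#' @export
schedule_ledger <- function(sched) {
  if (!inherits(sched, "network_schedule"))
    stop("schedule_ledger: need a network_schedule")
  ma <- numeric(nrow(sched))
  pp <- numeric(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    l <- sched[i, ]
    ma[i] <- switch(l$kind,
      standard  = l$d_out^2 * l$k^2 * l$c_in * l$c_out,
      depthwise = l$d_out^2 * l$k^2 * l$c_in,
      pointwise = l$d_out^2 * l$c_in * l$c_out,
      fc        = l$c_in * l$c_out)
    pp[i] <- switch(l$kind,
      standard  = l$k^2 * l$c_in * l$c_out,
      depthwise = l$k^2 * l$c_in,
      pointwise = l$c_in * l$c_out,
      fc        = l$c_in * l$c_out)
  }
  out <- cbind(as.data.frame(sched), multadds = ma, params = pp)
  frac_ma <- tapply(ma, sched$kind, sum) / sum(ma)
  frac_pp <- tapply(pp, sched$kind, sum) / sum(pp)
  attr(out, "totals") <- list(
    multadds = sum(ma), params = sum(pp),
    multadd_fraction = frac_ma, param_fraction = frac_pp)
  out
}

#' The MobileNet-v1 schedule (224 x 224 input)
#'
#' Frozen as a named constant: 3x3/32 stride-2 stem, thirteen
#' depthwise-separable blocks (channels 32-64-128-128-256-256-512,
#' five 512 blocks, 1024-1024; strides 1,2,1,2,1,2,1,1,1,1,1,2,1), and
#' the final 1024-to-1000 fully-connected classifier. About 95% of its
#' multiply-adds come from the 1x1 pointwise convolutions.
#'
#' @return A [network_schedule()].
#' @export
#' @examples
#' led <- schedule_ledger(mobilenet_v1_schedule())
#' attr(led, "totals")$multadd_fraction[["pointwise"]]
mobilenet_v1_schedule <- function() {
  ch  <- c(64, 128, 128, 256, 256, 512, 512, 512, 512, 512, 512, 1024, 1024)
  st  <- c(1, 2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 2, 1)
  kind <- "standard"; d_in <- 224; k <- 3; c_in <- 3; c_out <- 32; stride <- 2
  d <- 112; cprev <- 32
  for (i in seq_along(ch)) {
    kind <- c(kind, "depthwise", "pointwise")
    d_in <- c(d_in, d, ceiling(d / st[i]))
    k    <- c(k, 3, 1)
    c_in <- c(c_in, cprev, cprev)
    c_out <- c(c_out, cprev, ch[i])
    stride <- c(stride, st[i], 1)
    d <- ceiling(d / st[i])
    cprev <- ch[i]
  }
  kind <- c(kind, "fc"); d_in <- c(d_in, 1); k <- c(k, 1)
  c_in <- c(c_in, 1024); c_out <- c(c_out, 1000); stride <- c(stride, 1)
  network_schedule(kind, d_in, k, c_in, c_out, stride)
}
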