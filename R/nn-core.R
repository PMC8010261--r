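# Minimal dense neural-network engine used by the pruning, cascade and
# saliency modules. Design constraints that shape the code:
#   * batches are matrices (features x samples) so every layer is a BLAS
#     matrix product; convolution is im2col with integer index maps and a
#     sparse scatter matrix for the backward pass;
#   * feature layout within a sample is position-major within channel:
#     linear index = pos + (channel - 1) * n_positions;
#   * layers are plain lists; a model is a list of layers plus metadata,
#     so masking/materializing pruned channels is ordinary list surgery.

# ---- geometry ---------------------------------------------------------

# valid (no padding) convolution geometry for arbitrary spatial rank.
# Returns the im2col gather index vector and the transposed scatter
# operator used by the backward pass. Cached per process: identical
# block shapes recur hundreds of times during cascade training.
.geom_cache <- new.env(parent = emptyenv())

.conv_geom <- function(in_sp, c_in, k, stride = 1) {
  k <- rep_len(k, length(in_sp)); stride <- rep_len(stride, length(in_sp))
  key <- paste(c(in_sp, c_in, k, stride), collapse = "x")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  out_sp <- (in_sp - k) %/% stride + 1
  if (any(out_sp < 1))
    stop(sprintf("kernel (%s) larger than input (%s)",
                 paste(k, collapse = "x"), paste(in_sp, collapse = "x")))
  S <- prod(in_sp); P <- prod(out_sp); K <- prod(k)
  mult <- cumprod(c(1, in_sp))[seq_along(in_sp)]
  offs_grid <- as.matrix(do.call(expand.grid, lapply(k, function(d) 0:(d - 1))))
  k_off <- as.integer(offs_grid %*% mult)                      # K offsets
  org_grid <- as.matrix(do.call(expand.grid, mapply(
    function(o, s) seq(0L, by = s, length.out = o), out_sp, stride,
    SIMPLIFY = FALSE)))
  p_off <- as.integer(org_grid %*% mult)                       # P origins
  base <- outer(k_off, p_off, `+`) + 1L                        # K x P
  if (c_in > 1) {
    ch <- (seq_len(c_in) - 1L) * as.integer(S)
    idx <- base[rep(seq_len(K), c_in), , drop = FALSE] +
      rep(ch, each = K)                                        # (K*c_in) x P
  } else idx <- base
  idxvec <- as.integer(idx)
  scatter <- Matrix::sparseMatrix(i = idxvec, j = seq_along(idxvec), x = 1,
                                  dims = c(S * c_in, length(idxvec)))
  g <- list(in_sp = in_sp, out_sp = out_sp, c_in = c_in, k = k,
            stride = stride, S = S, P = P, K = K, KC = K * c_in,
            idxvec = idxvec, scatter = scatter)
  .geom_cache[[key]] <- g
  g
}

# ---- layers -----------------------------------------------------------

nn_conv <- function(in_sp, c_in, c_out, k = 3, stride = 1) {
  g <- .conv_geom(in_sp, c_in, k, stride)
  list(type = "conv", geom = g, c_out = c_out,
       W = matrix(0, g$KC, c_out), b = numeric(c_out),
       in_dim = g$S * c_in, out_dim = g$P * c_out)
}

nn_depthwise <- function(in_sp, channels, k = 3, stride = 1) {
  g <- .conv_geom(in_sp, 1L, k, stride)
  list(type = "depthwise", geom = g, channels = channels,
       W = matrix(0, g$K, channels), b = numeric(channels),
       in_dim = g$S * channels, out_dim = g$P * channels)
}

nn_pointwise <- function(n_pos, c_in, c_out) {
  list(type = "pointwise", P = n_pos, c_in = c_in, c_out = c_out,
       W = matrix(0, c_in, c_out), b = numeric(c_out),
       in_dim = n_pos * c_in, out_dim = n_pos * c_out)
}

nn_fc <- function(n_in, n_out) {
  list(type = "fc", W = matrix(0, n_in, n_out), b = numeric(n_out),
       in_dim = n_in, out_dim = n_out)
}

nn_relu <- function(n) list(type = "relu", in_dim = n, out_dim = n)

# mean pooling by integer factor per axis (truncating at the boundary)
nn_pool <- function(in_sp, channels, f = 2) {
  f <- rep_len(f, length(in_sp))
  out_sp <- in_sp %/% f
  S <- prod(in_sp); P <- prod(out_sp)
  mult_in <- cumprod(c(1, in_sp))[seq_along(in_sp)]
  cell <- as.matrix(do.call(expand.grid, lapply(f, function(d) 0:(d - 1))))
  cell_off <- as.integer(cell %*% mult_in)
  org <- as.matrix(do.call(expand.grid, mapply(
    function(o, s) seq(0L, by = s, length.out = o), out_sp, f,
    SIMPLIFY = FALSE)))
  org_off <- as.integer(org %*% mult_in)
  src <- as.integer(outer(cell_off, org_off, `+`)) + 1L   # prod(f) x P
  j1 <- rep(seq_len(P), each = prod(f))
  blocks <- lapply(seq_len(channels), function(c)
    Matrix::sparseMatrix(i = j1 + (c - 1L) * P, j = src + (c - 1L) * S,
                         x = 1 / prod(f), dims = c(P * channels, S * channels)))
  M <- Reduce(`+`, blocks)
  list(type = "pool", M = M, in_dim = S * channels, out_dim = P * channels,
       out_sp = out_sp, channels = channels, in_sp = in_sp, f = f)
}

# fixed (non-trainable) input standardization: (x - mu) / s
nn_norm <- function(mu, s, n = length(mu)) {
  stopifnot(s > 0)
  list(type = "norm", mu = mu, inv_s = 1 / s, in_dim = n, out_dim = n)
}

nn_gap <- function(n_pos, channels) {
  list(type = "gap", P = n_pos, channels = channels,
       in_dim = n_pos * channels, out_dim = channels)
}

# ---- model ------------------------------------------------------------

nn_model <- function(layers, meta = list()) {
  for (i in seq_along(layers)[-1]) {
    if (layers[[i]]$in_dim != layers[[i - 1]]$out_dim)
      stop(sprintf("nn_model: layer %d expects %d inputs, layer %d outputs %d",
                   i, layers[[i]]$in_dim, i - 1, layers[[i - 1]]$out_dim))
  }
  structure(list(layers = layers, meta = meta), class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %d layers: %s\n", length(x$layers),
              paste(vapply(x$layers, `[[`, "", "type"), collapse = " -> ")))
  invisible(x)
}

# Xavier/Glorot uniform initialization; biases zero
nn_init_xavier <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model$layers <- lapply(model$layers, function(l) {
    if (!is.null(l$W)) {
      fan_in <- nrow(l$W)
      fan_out <- if (l$type == "depthwise") nrow(l$W) else ncol(l$W)
      lim <- sqrt(6 / (fan_in + fan_out))
      l$W <- matrix(stats::runif(length(l$W), -lim, lim), nrow(l$W), ncol(l$W))
      l$b <- numeric(length(l$b))
    }
    l
  })
  model
}

.fwd_layer <- function(l, X) {
  B <- ncol(X)
  switch(l$type,
    conv = {
      g <- l$geom
      cols <- matrix(X[g$idxvec, ], g$KC, g$P * B)
      Z <- crossprod(l$W, cols) + l$b
      Y <- aperm(array(Z, c(l$c_out, g$P, B)), c(2, 1, 3))
      dim(Y) <- c(g$P * l$c_out, B)
      Y
    },
    depthwise = {
      g <- l$geom
      Y <- matrix(0, g$P * l$channels, B)
      for (c in seq_len(l$channels)) {
        Xc <- X[((c - 1) * g$S + 1):(c * g$S), , drop = FALSE]
        cols <- matrix(Xc[g$idxvec, ], g$K, g$P * B)
        Y[((c - 1) * g$P + 1):(c * g$P), ] <-
          matrix(crossprod(l$W[, c, drop = FALSE], cols) + l$b[c], g$P, B)
      }
      Y
    },
    pointwise = {
      Xa <- aperm(array(X, c(l$P, l$c_in, B)), c(1, 3, 2))
      dim(Xa) <- c(l$P * B, l$c_in)
      Z <- Xa %*% l$W
      Z <- sweep(Z, 2, l$b, `+`)
      Y <- aperm(array(Z, c(l$P, B, l$c_out)), c(1, 3, 2))
      dim(Y) <- c(l$P * l$c_out, B)
      Y
    },
    fc = crossprod(l$W, X) + l$b,
    norm = (X - l$mu) * l$inv_s,
    relu = pmax(X, 0),
    pool = as.matrix(l$M %*% X),
    gap = {
      Xa <- array(X, c(l$P, l$channels * B))
      matrix(colMeans(Xa), l$channels, B)
    },
    stop("unknown layer type ", l$type))
}

.bwd_layer <- function(l, X, dY) {
  B <- ncol(X)
  switch(l$type,
    conv = {
      g <- l$geom
      dZ <- aperm(array(dY, c(g$P, l$c_out, B)), c(2, 1, 3))
      dim(dZ) <- c(l$c_out, g$P * B)
      cols <- matrix(X[g$idxvec, ], g$KC, g$P * B)
      dW <- tcrossprod(cols, dZ)
      db <- rowSums(dZ)
      dcols <- l$W %*% dZ
      dim(dcols) <- c(g$KC * g$P, B)
      dX <- as.matrix(g$scatter %*% dcols)
      list(dX = dX, dW = dW, db = db)
    },
    depthwise = {
      g <- l$geom
      dW <- matrix(0, g$K, l$channels); db <- numeric(l$channels)
      dX <- matrix(0, nrow(X), B)
      for (c in seq_len(l$channels)) {
        Xc <- X[((c - 1) * g$S + 1):(c * g$S), , drop = FALSE]
        cols <- matrix(Xc[g$idxvec, ], g$K, g$P * B)
        dZc <- matrix(dY[((c - 1) * g$P + 1):(c * g$P), , drop = FALSE],
                      1, g$P * B)
        dW[, c] <- tcrossprod(cols, dZc)
        db[c] <- sum(dZc)
        dcols <- l$W[, c, drop = FALSE] %*% dZc
        dim(dcols) <- c(g$K * g$P, B)
        dX[((c - 1) * g$S + 1):(c * g$S), ] <- as.matrix(g$scatter %*% dcols)
      }
      list(dX = dX, dW = dW, db = db)
    },
    pointwise = {
      Xa <- aperm(array(X, c(l$P, l$c_in, B)), c(1, 3, 2))
      dim(Xa) <- c(l$P * B, l$c_in)
      dZ <- aperm(array(dY, c(l$P, l$c_out, B)), c(1, 3, 2))
      dim(dZ) <- c(l$P * B, l$c_out)
      dW <- crossprod(Xa, dZ)
      db <- colSums(dZ)
      dXa <- tcrossprod(dZ, l$W)
      dX <- aperm(array(dXa, c(l$P, B, l$c_in)), c(1, 3, 2))
      dim(dX) <- c(l$P * l$c_in, B)
      list(dX = dX, dW = dW, db = db)
    },
    fc = list(dX = l$W %*% dY, dW = tcrossprod(X, dY), db = rowSums(dY)),
    norm = list(dX = dY * l$inv_s),
    relu = list(dX = dY * (X > 0)),
    pool = list(dX = as.matrix(Matrix::crossprod(l$M, dY))),
    gap = {
      dX <- dY[rep(seq_len(l$channels), each = l$P), , drop = FALSE] / l$P
      list(dX = dX)
    })
}

# forward pass; acts[[i]] is the OUTPUT of layer i (acts[[0]] impossible,
# the input itself is returned as $input)
nn_forward <- function(model, X) {
  acts <- vector("list", length(model$layers))
  cur <- X
  for (i in seq_along(model$layers)) {
    cur <- .fwd_layer(model$layers[[i]], cur)
    acts[[i]] <- cur
  }
  list(out = cur, acts = acts, input = X)
}

#' Softmax probabilities from logits
#'
#' The normalized exponential `exp(z_j) / sum_k exp(z_k)`, stabilized by
#' subtracting the column maximum, hence invariant to adding a constant
#' to all logits.
#'
#' @param z Numeric vector of logits, or a matrix with one logit vector
#'   per column.
#' @return Probabilities of the same shape; columns sum to 1.
#' @export
#' @examples
#' softmax(c(1, 2, 3))
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- sweep(z, 2, apply(z, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), `/`)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Cross-entropy loss
#'
#' `L = -sum_i t_i * log(y_i)` for a probability vector `y` and one-hot
#' (or soft) label `t`; zero exactly when `y` puts all mass on the true
#' class. Probabilities are clamped below at `eps` so a zero probability
#' at the true class yields a large finite loss.
#'
#' @param y Predicted probability vector (or matrix, one column per
#'   sample).
#' @param t One-hot label vector (or matrix of matching shape).
#' @param eps Clamp floor for `log` (default `1e-12`).
#' @return Loss value (mean over columns when matrices are supplied).
#' @export
#' @examples
#' cross_entropy(c(0.25, 0.25, 0.5), c(0, 0, 1))
cross_entropy <- function(y, t, eps = 1e-12) {
  y <- pmax(y, eps)
  if (is.matrix(y)) mean(-colSums(t * log(y))) else -sum(t * log(y))
}

# softmax + cross-entropy on logits; returns loss and dLogits (averaged
# over the batch)
.softmax_ce <- function(logits, T1hot) {
  P <- softmax(logits)
  loss <- cross_entropy(P, T1hot)
  list(loss = loss, probs = P, dlogits = (P - T1hot) / ncol(logits))
}

nn_backprop <- function(model, fwd, dOut) {
  L <- length(model$layers)
  grads <- vector("list", L)
  d <- dOut
  for (i in rev(seq_len(L))) {
    Xin <- if (i == 1) fwd$input else fwd$acts[[i - 1]]
    g <- .bwd_layer(model$layers[[i]], Xin, d)
    grads[[i]] <- g[c("dW", "db")]
    d <- g$dX
  }
  grads
}

# ---- training ---------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the training protocol used throughout the package:
#' Adadelta (rho 0.95, eps 1e-6), batch size 64, Xavier initialization.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (default 64).
#' @param rho,eps Adadelta decay and stabilizer.
#' @param weight_decay L2 penalty added to weight gradients (biases
#'   exempt).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 15, batch_size = 64, rho = 0.95,
                         eps = 1e-6, weight_decay = 0, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, weight_decay >= 0)
  structure(list(epochs = epochs, batch_size = batch_size, rho = rho,
                 eps = eps, weight_decay = weight_decay, seed = seed),
            class = "train_config")
}

.adadelta_state <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(Eg_W = l$W * 0, Ed_W = l$W * 0,
         Eg_b = l$b * 0, Ed_b = l$b * 0)
  })
}

.adadelta_step <- function(val, grad, Eg, Ed, rho, eps) {
  Eg <- rho * Eg + (1 - rho) * grad^2
  upd <- -sqrt(Ed + eps) / sqrt(Eg + eps) * grad
  Ed <- rho * Ed + (1 - rho) * upd^2
  list(val = val + upd, Eg = Eg, Ed = Ed)
}

# one-hot encode integer labels 1..C
.one_hot <- function(y, C) {
  T1 <- matrix(0, C, length(y))
  T1[cbind(y, seq_along(y))] <- 1
  T1
}

# Train a classifier by Adadelta on softmax cross-entropy.
# masks: optional per-layer list(W=, b=) of 0/1 matrices; zeroed entries
# receive no gradient updates (used by channel pruning).
nn_train <- function(model, X, y, cfg = train_config(), masks = NULL,
                     verbose = FALSE) {
  C <- model$layers[[length(model$layers)]]$out_dim
  T1 <- .one_hot(y, C)
  st <- .adadelta_state(model)
  n <- ncol(X)
  set.seed(cfg$seed)
  history <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1, n)]
      fwd <- nn_forward(model, X[, sel, drop = FALSE])
      sc <- .softmax_ce(fwd$out, T1[, sel, drop = FALSE])
      if (!is.finite(sc$loss))
        stop("nn_train: non-finite loss at epoch ", ep)
      grads <- nn_backprop(model, fwd, sc$dlogits)
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]]$dW)) next
        gW <- grads[[i]]$dW; gb <- grads[[i]]$db
        if (cfg$weight_decay > 0)
          gW <- gW + cfg$weight_decay * model$layers[[i]]$W
        if (!is.null(masks) && !is.null(masks[[i]])) {
          gW <- gW * masks[[i]]$W
          gb <- gb * masks[[i]]$b
        }
        sW <- .adadelta_step(model$layers[[i]]$W, gW, st[[i]]$Eg_W,
                             st[[i]]$Ed_W, cfg$rho, cfg$eps)
        model$layers[[i]]$W <- sW$val
        st[[i]]$Eg_W <- sW$Eg; st[[i]]$Ed_W <- sW$Ed
        sb <- .adadelta_step(model$layers[[i]]$b, gb, st[[i]]$Eg_b,
                             st[[i]]$Ed_b, cfg$rho, cfg$eps)
        model$layers[[i]]$b <- sb$val
        st[[i]]$Eg_b <- sb$Eg; st[[i]]$Ed_b <- sb$Ed
      }
      ep_loss <- ep_loss + sc$loss; nb <- nb + 1
    }
    history <- c(history, ep_loss / nb)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, ep_loss / nb))
  }
  model$meta$history <- history
  model
}

# class probabilities (C x B)
#' Serialize a model to portable text
#'
#' Architecture and weights are written as a single JSON document
#' (full double precision); [nn_load()] reconstructs the model,
#' including convolution geometry. Sufficient for the package's dense
#' models; not a general interchange format.
#'
#' @param model An `nn_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
nn_save <- function(model, path) {
  ser <- list(meta = model$meta,
              layers = lapply(model$layers, function(l) {
    out <- list(type = l$type)
    if (!is.null(l$W)) { out$W <- l$W; out$b <- l$b }
    out$spec <- switch(l$type,
      conv = list(in_sp = l$geom$in_sp, c_in = l$geom$c_in, k = l$geom$k,
                  stride = l$geom$stride, c_out = l$c_out),
      depthwise = list(in_sp = l$geom$in_sp, channels = l$channels,
                       k = l$geom$k, stride = l$geom$stride),
      pointwise = list(P = l$P, c_in = l$c_in, c_out = l$c_out),
      fc = list(n_in = nrow(l$W), n_out = ncol(l$W)),
      relu = list(n = l$in_dim),
      norm = list(mu = l$mu, inv_s = l$inv_s, n = l$in_dim),
      pool = list(in_sp = l$in_sp, channels = l$channels, f = l$f),
      gap = list(P = l$P, channels = l$channels))
    out
  }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized by [nn_save()]
#'
#' @param path JSON path.
#' @return An `nn_model`.
#' @export
nn_load <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(ser$layers, function(lr) {
    sp <- lapply(lr$spec, unlist)
    l <- switch(lr$type,
      conv = nn_conv(sp$in_sp, sp$c_in, sp$c_out, sp$k, sp$stride),
      depthwise = nn_depthwise(sp$in_sp, sp$channels, sp$k, sp$stride),
      pointwise = nn_pointwise(sp$P, sp$c_in, sp$c_out),
      fc = nn_fc(sp$n_in, sp$n_out),
      relu = nn_relu(sp$n),
      norm = nn_norm(sp$mu, 1 / sp$inv_s, sp$n),
      pool = nn_pool(sp$in_sp, sp$channels, sp$f),
      gap = nn_gap(sp$P, sp$channels),
      stop("nn_load: unknown layer type ", lr$type))
    if (!is.null(lr$W)) {
      # jsonlite writes matrices row-major (array of rows)
      l$W <- matrix(unlist(lr$W), nrow(l$W), ncol(l$W), byrow = TRUE)
      l$b <- as.numeric(unlist(lr$b))
    }
    l
  })
  # JSON arrays (unnamed lists of scalars) back to atomic vectors;
  # named objects and arrays-of-objects keep their list structure
  fix <- function(x) {
    if (!is.list(x)) return(x)
    if (is.null(names(x)) && length(x) &&
        all(vapply(x, function(e) !is.list(e) && length(e) == 1, TRUE)))
      return(unlist(x))
    lapply(x, fix)
  }
  meta <- fix(ser$meta)
  nn_model(layers, if (is.null(meta)) list() else meta)
}

nn_predict <- function(model, X, batch = 256) {
  n <- ncol(X)
  out <- NULL
  for (start in seq(1, n, by = batch)) {
    sel <- start:min(start + batch - 1, n)
    p <- softmax(nn_forward(model, X[, sel, drop = FALSE])$out)
    out <- if (is.null(out)) p else cbind(out, p)
  }
  out
}

nn_accuracy <- function(model, X, y) {
  p <- nn_predict(model, X)
  mean(max.col(t(p)) == y)
}
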