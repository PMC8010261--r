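# Independent brute-force oracles. These are deliberately naive and
# share no code with the package: shortest paths by exhaustive simple-
# path enumeration, Pearson correlation by the textbook formula, Welch
# t by its closed form, and convolution costs by explicit loops.

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# all simple paths j -> k in an undirected weighted graph, with edge
# lengths 1/weight; returns list(min_len, n_shortest, n_through[i])
oracle_paths <- function(w, j, k, tol = 1e-9) {
  n <- nrow(w)
  best <- Inf; paths <- list()
  walk <- function(v, visited, len) {
    if (v == k) {
      if (len < best - tol) { best <<- len; paths <<- list(visited) }
      else if (abs(len - best) <= tol) paths[[length(paths) + 1]] <<- visited
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !(u %in% visited)) {
        l2 <- len + 1 / w[v, u]
        if (l2 <= best + tol) walk(u, c(visited, u), l2)
      }
    }
  }
  walk(j, j, 0)
  list(min_len = best, n = length(paths), paths = paths)
}

oracle_degree <- function(w, i) sum(w[i, ])

oracle_efficiency <- function(w, i) {
  nb <- which(w[i, ] > 0)
  m <- length(nb)
  if (m < 2) return(0)
  sub <- w[nb, nb, drop = FALSE]
  tot <- 0
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    sp <- oracle_paths(sub, a, b)
    if (is.finite(sp$min_len)) tot <- tot + 1 / sp$min_len
  }
  tot / (m * (m - 1))
}

oracle_betweenness <- function(w, i) {
  n <- nrow(w)
  tot <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (j == i || k == i) next
    sp <- oracle_paths(w, j, k)
    if (!is.finite(sp$min_len) || sp$n == 0) next
    through <- sum(vapply(sp$paths, function(p) i %in% p[-c(1, length(p))],
                          logical(1)))
    tot <- tot + through / sp$n
  }
  tot
}

# random sparse symmetric weight matrix on n nodes
random_graph <- function(n, p = 0.45, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < p]
  w[on] <- stats::runif(length(on), 0.2, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

# explicit multiply counting for a square conv layer at the ledger's
# "same padding, ceil-division stride" convention
oracle_layer_multiplies <- function(kind, d_in, k, c_in, c_out, stride = 1) {
  d_out <- ceiling(d_in / stride)
  count <- 0
  for (ox in seq_len(d_out)) for (oy in seq_len(d_out)) {
    count <- count + switch(kind,
      standard  = k * k * c_in * c_out,
      depthwise = k * k * c_in,
      pointwise = c_in * c_out)
  }
  count
}

oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, p = p)
}
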