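#' Remove unstable initial fMRI volumes
#'
#' The first few BOLD volumes of an fMRI acquisition are unreliable
#' (unstable blood-oxygen signal) and are discarded before any
#' correlation analysis. Default is the conventional 5 volumes.
#'
#' @param series Either a `regions x timepoints` matrix (a time-series
#'   matrix, timepoints in columns) or a 4D array whose last dimension
#'   is time.
#' @param k Number of initial timepoints to remove (default 5).
#' @return Same type as `series` with the first `k` timepoints removed.
#' @export
#' @examples
#' trim_initial_volumes(matrix(rnorm(52 * 140), 52, 140))  # 52 x 135
trim_initial_volumes <- function(series, k = 5) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k))
    stop("trim_initial_volumes: k must be a single nonnegative integer")
  nd <- length(dim(series))
  nt <- if (nd == 4) dim(series)[4] else ncol(series)
  if (is.null(nt))
    stop("trim_initial_volumes: need a matrix or 4D array")
  if (nt <= k)
    stop(sprintf("trim_initial_volumes: series has %d timepoints, cannot remove k = %d",
                 nt, k))
  if (k == 0) return(series)
  if (nd == 4) series[, , , (k + 1):nt, drop = FALSE]
  else series[, (k + 1):nt, drop = FALSE]
}

#' Functional-connectivity matrix from region time series
#'
#' Pearson correlation of region-mean BOLD time series:
#' `fc[a, b] = Cov(a, b) / sqrt(var(a) * var(b))` over the full time
#' window. Rows of `ts` are regions, columns timepoints.
#'
#' @param ts Numeric `regions x timepoints` matrix; row names are taken
#'   as region labels.
#' @return An `fc_matrix`: symmetric correlation matrix with unit
#'   diagonal and entries in `[-1, 1]`.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("compute_fc: need at least 3 timepoints")
  if (anyNA(ts)) stop("compute_fc: missing values in time series")
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    lb <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stop("compute_fc: zero-variance region(s): ", paste(lb, collapse = ", "))
  }
  fc <- stats::cor(t(ts))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  dimnames(fc) <- list(rownames(ts), rownames(ts))
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((eta_k - eta_bar)^2)) / sqrt(sum(eta_k^2))`
#' where `eta_bar` is the eigenvalue mean. FA is 0 for isotropic
#' diffusion (all eigenvalues equal) and 1 for fully anisotropic
#' diffusion (a single nonzero eigenvalue), and is invariant to overall
#' scaling of the eigenvalues.
#'
#' @param eig Numeric vector of the three nonnegative eigenvalues (any
#'   order; they are sorted internally).
#' @return FA value in `[0, 1]`.
#' @export
#' @examples
#' fa_from_eigenvalues(c(1, 1, 1))  # 0
#' fa_from_eigenvalues(c(1, 0, 0))  # 1
fa_from_eigenvalues <- function(eig) {
  if (length(eig) != 3 || anyNA(eig) || any(eig < 0))
    stop("fa_from_eigenvalues: need three nonnegative eigenvalues")
  if (all(eig == 0))
    stop("fa_from_eigenvalues: FA undefined for an all-zero eigenvalue triple")
  eig <- sort(as.numeric(eig), decreasing = TRUE)
  fa <- sqrt(3 / 2) * sqrt(sum((eig - mean(eig))^2)) / sqrt(sum(eig^2))
  min(max(fa, 0), 1)
}

new_brain_network <- function(weights, modality, labels = NULL) {
  n <- nrow(weights)
  diag(weights) <- 0
  weights <- (weights + t(weights)) / 2
  if (!is.null(labels)) dimnames(weights) <- list(labels, labels)
  structure(list(n_nodes = n, weights = weights, modality = modality),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %s: %d nodes, %d edges\n", x$modality,
              x$n_nodes, sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Build a functional connectivity network (FCN)
#'
#' An edge is kept between two regions only where the correlation
#' exceeds `threshold`; its weight is the correlation value. The
#' correlation threshold is not a canonical constant (default 0.3 is an
#' artifact default, prominently configurable). Negative correlations
#' are dropped by default; `negative = "absolute"` keeps them with
#' absolute-value weights.
#'
#' @param fc An [compute_fc()] matrix.
#' @param threshold Correlation cutoff in `[0, 1)`; strict `>` rule.
#' @param negative `"drop"` (default) or `"absolute"`.
#' @return A `brain_network` with `modality = "FCN"`.
#' @export
build_fcn <- function(fc, threshold = 0.3, negative = c("drop", "absolute")) {
  negative <- match.arg(negative)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("build_fcn: threshold must lie in [0, 1)")
  w <- unclass(as.matrix(fc))
  if (negative == "absolute") w <- abs(w)
  w[w <= threshold] <- 0
  new_brain_network(w, "FCN", rownames(fc))
}

#' Build a DTI structural connectivity network (DTISCN)
#'
#' Edges are weighted by regional fractional anisotropy; FA below the
#' conventional 0.2 cutoff means no reliable white-matter fibers, so
#' those entries (and absent/`NA` entries) carry no edge. The rule is
#' inclusive: FA exactly 0.2 keeps its edge. Larger FA means stronger
#' fiber connection.
#'
#' @param fa Symmetric `regions x regions` FA matrix; `NA` marks absent
#'   entries.
#' @param fa_threshold FA cutoff (default 0.2, inclusive).
#' @return A `brain_network` with `modality = "DTISCN"`.
#' @export
build_dtiscn <- function(fa, fa_threshold = 0.2) {
  w <- as.matrix(fa)
  if (nrow(w) != ncol(w)) stop("build_dtiscn: FA matrix must be square")
  ok <- !is.na(w)
  if (any(w[ok] < 0 | w[ok] > 1))
    stop("build_dtiscn: present FA entries must lie in [0, 1]")
  w[!ok] <- 0
  w[w < fa_threshold] <- 0
  new_brain_network(w, "DTISCN", rownames(fa))
}

# edge lengths for shortest paths: strong connections are short
.edge_lengths <- function(w) {
  len <- 1 / w
  len[w == 0] <- Inf
  diag(len) <- 0
  len
}

.as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# dense Floyd-Warshall on a length matrix (Inf = no edge)
.shortest_lengths <- function(len) {
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

#' Weighted node degree
#'
#' Sum of the weights of the edges incident to node `i` (node strength).
#'
#' @param net A `brain_network`.
#' @param i Node index (1-based) or `NULL` for all nodes.
#' @return Degree value(s).
#' @export
node_degree <- function(net, i = NULL) {
  d <- rowSums(net$weights)
  if (is.null(i)) d else { stopifnot(i >= 1, i <= net$n_nodes); d[i] }
}

#' Weighted local node efficiency
#'
#' Over the subgraph induced by node `i`'s neighbors, the mean inverse
#' shortest-path length across ordered pairs:
#' `E_i = sum_{j != k} (1 / L_jk) / (N_Gi * (N_Gi - 1))`, with path
#' lengths computed on edge lengths `1/weight` and disconnected pairs
#' contributing 0. Nodes with fewer than two neighbors have efficiency
#' 0 (the normalization is otherwise undefined).
#'
#' @inheritParams node_degree
#' @return Efficiency value(s).
#' @export
node_efficiency <- function(net, i = NULL) {
  w <- net$weights
  idx <- if (is.null(i)) seq_len(net$n_nodes) else i
  out <- vapply(idx, function(v) {
    nb <- which(w[v, ] > 0)
    m <- length(nb)
    if (m < 2) return(0)
    d <- .shortest_lengths(.edge_lengths(w[nb, nb, drop = FALSE]))
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  if (is.null(i)) out else out[1]
}

#' Weighted betweenness centrality
#'
#' For every unordered node pair `{j, k}` (both different from `i`),
#' the fraction of shortest paths between them passing through `i` as
#' an interior node, summed over pairs; unnormalized. Shortest paths
#' use edge lengths `1/weight`; pairs with no connecting path
#' contribute 0.
#'
#' @inheritParams node_degree
#' @return Betweenness value(s).
#' @export
betweenness_centrality <- function(net, i = NULL) {
  g <- .as_igraph(net)
  ew <- 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = ew)
  b <- as.numeric(b)
  if (is.null(i)) b else { stopifnot(i >= 1, i <= net$n_nodes); b[i] }
}

#' Graph-theory feature vector for one subject
#'
#' Concatenates node degree, local efficiency and betweenness
#' centrality over the supplied networks, in deterministic
#' `(modality, metric, node)` order. With the default 52-region
#' parcellation and both FCN and DTISCN networks the vector has
#' length `3 * 52 * 2 = 312`.
#'
#' @param networks A list of `brain_network` objects (e.g.
#'   `list(fcn, dtiscn)`); all must share node count.
#' @return Named numeric vector.
#' @export
extract_features <- function(networks) {
  if (inherits(networks, "brain_network")) networks <- list(networks)
  if (length(networks) == 0) stop("extract_features: no networks supplied")
  nn <- vapply(networks, function(x) x$n_nodes, numeric(1))
  if (length(unique(nn)) != 1)
    stop("extract_features: networks disagree on node count (",
         paste(nn, collapse = " vs "), ")")
  out <- unlist(lapply(networks, function(net) {
    vals <- c(node_degree(net), node_efficiency(net),
              betweenness_centrality(net))
    names(vals) <- paste(net$modality,
                         rep(c("degree", "efficiency", "betweenness"),
                             each = net$n_nodes),
                         rep(seq_len(net$n_nodes), times = 3), sep = ".")
    vals
  }))
  if (any(!is.finite(out))) stop("extract_features: non-finite feature value")
  out
}

#' Two-sample feature selection by Welch t-test
#'
#' Applies a two-sided Welch (unequal-variance) t-test to every feature
#' column and flags features with `p < alpha` as selected. Optional
#' Benjamini-Hochberg correction operates on the p-values before the
#' threshold is applied.
#'
#' @param group_a,group_b Numeric `subjects x features` matrices (or
#'   data frames) with matching columns.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default) or `"BH"`.
#' @return A data frame with `feature`, `t`, `p`, `p_adj`, `selected`,
#'   and attribute `alpha`.
#' @export
ttest_select <- function(group_a, group_b, alpha = 0.05,
                         correction = c("none", "BH")) {
  correction <- match.arg(correction)
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (ncol(a) != ncol(b)) stop("ttest_select: feature columns differ")
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("ttest_select: need at least 2 subjects per group")
  res <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(c(t = 0, p = 1))  # degenerate: no variance anywhere
    ht <- stats::t.test(x, y, var.equal = FALSE)
    c(t = unname(ht$statistic), p = ht$p.value)
  }, c(t = 0, p = 0))
  p_adj <- stats::p.adjust(res["p", ], method = if (correction == "BH") "BH" else "none")
  out <- data.frame(
    feature = if (!is.null(colnames(a))) colnames(a) else paste0("f", seq_len(ncol(a))),
    t = res["t", ], p = res["p", ], p_adj = p_adj,
    selected = p_adj < alpha, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  out
}
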