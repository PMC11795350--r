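#' Proportional thresholding of a connectivity matrix
#'
#' Ranks the upper-triangle weights in descending order and retains the top
#' `floor(proportion * n_pairs)` edges (default 55% of the 435 pairs of a
#' 30-node network, i.e. 239 edges), zeroing the rest and symmetrizing.
#' Ties at the cut are broken by ascending (row, column) index so the
#' result is deterministic. Retained weights are unchanged.
#'
#' @param mat symmetric numeric matrix with zero diagonal (e.g. a
#'   [aggregate_band()] result).
#' @param proportion fraction of edges to retain, in (0, 1\]; default 0.55.
#' @return An object of class `thresholded_graph`: a list with `weights`
#'   (thresholded matrix), `proportion`, `retained_edges`, `labels`.
#' @export
threshold_proportional <- function(mat, proportion = 0.55) {
  mat <- unclass(mat)
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-10))) {
    stop("input matrix must be symmetric")
  }
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop("proportion must be in (0, 1]")
  }
  n <- nrow(mat)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  w <- mat[upper.tri(mat)]
  keep_n <- floor(proportion * length(w))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(keep_n)]
  out <- matrix(0, n, n, dimnames = dimnames(mat))
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out <- out + t(out)
  structure(list(weights = out, proportion = proportion,
                 retained_edges = keep_n,
                 labels = rownames(mat) %||% as.character(seq_len(n))),
            class = "thresholded_graph")
}

#' Wrap a plain weight matrix as a thresholded graph
#'
#' Convenience constructor used for reference graphs and toy examples:
#' treats every nonzero entry as a retained edge.
#'
#' @param weights symmetric matrix with zero diagonal.
#' @return A `thresholded_graph`.
#' @export
as_thresholded_graph <- function(weights) {
  weights <- unclass(weights)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  structure(list(weights = weights, proportion = NA_real_,
                 retained_edges = sum(weights[upper.tri(weights)] != 0),
                 labels = rownames(weights) %||%
                   as.character(seq_len(nrow(weights)))),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("thresholded_graph: %d nodes, %d edges (proportion %s)\n",
              nrow(x$weights), x$retained_edges,
              ifelse(is.na(x$proportion), "-", x$proportion)))
  invisible(x)
}

# internal: weight matrix with guaranteed dimnames
named_weights <- function(g) {
  w <- g$weights
  if (is.null(dimnames(w))) dimnames(w) <- list(g$labels, g$labels)
  w
}

# internal: igraph object with edge attribute `dist` = 1/weight
as_igraph_dist <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(named_weights(g),
                                            mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::E(ig)$dist <- 1 / igraph::E(ig)$weight
  ig
}

#' Path-based integration metrics
#'
#' Characteristic path length and global efficiency of a thresholded
#' weighted graph. Shortest paths are computed on edge distances
#' `d = 1/w` (Dijkstra). `L` is the mean shortest-path distance over
#' connected node pairs; `E_glob` the mean of `1/d` over all pairs, with
#' disconnected pairs contributing 0. Disconnected graphs are flagged, not
#' an error.
#'
#' @param g a [threshold_proportional()] result (or [as_thresholded_graph()]).
#' @return A list: `L`, `E_glob`, `distances` (matrix), `disconnected`.
#' @export
path_metrics <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (all(g$weights == 0)) stop("edgeless graph: path metrics undefined")
  ig <- as_igraph_dist(g)
  d <- igraph::distances(ig, weights = igraph::E(ig)$dist)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  L <- mean(off[finite])
  E_glob <- mean(ifelse(finite, 1 / off, 0))
  list(L = L, E_glob = E_glob, distances = d,
       disconnected = !all(finite))
}

#' Weighted betweenness centrality
#'
#' Betweenness on shortest paths over edge distances `1/w`, with
#' fractional counting over equal-cost paths, normalized by
#' `(n-1)(n-2)/2` so values lie in \[0, 1\].
#'
#' @param g a `thresholded_graph`.
#' @return Named numeric vector of node betweenness values.
#' @export
betweenness_w <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  ig <- as_igraph_dist(g)
  b <- igraph::betweenness(ig, weights = igraph::E(ig)$dist,
                           normalized = TRUE)
  out <- stats::setNames(numeric(nrow(g$weights)), g$labels)
  out[names(b)] <- b
  out
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node weighted clustering as the geometric mean of triangle weights,
#' on weights rescaled by the global maximum:
#' \deqn{cc_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h} (\hat w_{ij} \hat w_{ih}
#' \hat w_{jh})^{1/3}} with \eqn{\hat w = w / \max(w)} and `k` the binary
#' degree. Nodes of degree < 2 have cc = 0.
#'
#' @param g a `thresholded_graph`.
#' @return A list: `cc` (named per-node vector), `C` (mean over all nodes).
#' @export
clustering_onnela <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  w <- g$weights
  mx <- max(w)
  if (mx == 0) {
    cc <- stats::setNames(numeric(nrow(w)), g$labels)
    return(list(cc = cc, C = 0))
  }
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wh %*% wh %*% wh)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(cc) <- g$labels
  list(cc = cc, C = mean(cc))
}

#' Community structure by weighted Louvain
#'
#' Seeded weighted Louvain partition with modularity `Q` and the
#' within-module strength z-score of every node (z = 0 in singleton
#' modules or modules with uniform within-module strength).
#'
#' @param g a `thresholded_graph`.
#' @param seed integer seed (Louvain is stochastic).
#' @param resolution resolution parameter (default 1).
#' @return A list: `membership` (named integer vector), `Q`, `module_z`
#'   (named numeric vector).
#' @export
communities_louvain <- function(g, seed = 1, resolution = 1) {
  stopifnot(inherits(g, "thresholded_graph"))
  ig <- igraph::graph_from_adjacency_matrix(named_weights(g),
                                            mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(ig, resolution = resolution)
  memb <- stats::setNames(rep(NA_integer_, nrow(g$weights)), g$labels)
  memb[igraph::V(ig)$name] <- igraph::membership(cl)
  # isolated nodes are absent from ig only if weights row is all zero;
  # graph_from_adjacency_matrix keeps all vertices, so memb is complete
  Q <- igraph::modularity(ig, igraph::membership(cl),
                          weights = igraph::E(ig)$weight)
  # within-module strength z-score
  z <- stats::setNames(numeric(length(memb)), names(memb))
  for (m in unique(memb)) {
    nodes <- which(memb == m)
    if (length(nodes) < 2) next
    s_in <- rowSums(g$weights[nodes, nodes, drop = FALSE])
    sdv <- sd(s_in)
    if (is.na(sdv) || sdv == 0) next
    z[nodes] <- (s_in - mean(s_in)) / sdv
  }
  list(membership = memb, Q = Q, module_z = z)
}

#' Participation coefficient and hub classification
#'
#' Participation coefficient
#' \deqn{P_i = 1 - \sum_m (s_{im}/s_i)^2}
#' where `s_i` is node strength and `s_im` the strength of node i's edges
#' into module m. Nodes with all strength inside their own module have
#' P = 0; zero-strength nodes are assigned P = 0 by convention. Nodes are
#' flagged as (connector) hubs when P exceeds `threshold`. The continuous
#' P is the analysis variable; the flag is reporting convenience.
#'
#' @param g a `thresholded_graph`.
#' @param membership named module membership covering all nodes (from
#'   [communities_louvain()]).
#' @param threshold hub threshold on P (default 0.3).
#' @return A list: `participation` (named numeric), `hub_flag` (named
#'   logical).
#' @export
hubness <- function(g, membership, threshold = 0.3) {
  stopifnot(inherits(g, "thresholded_graph"))
  n <- nrow(g$weights)
  if (length(membership) != n || anyNA(membership)) {
    stop("membership must cover all ", n, " nodes")
  }
  s <- rowSums(g$weights)
  mods <- sort(unique(membership))
  sm <- vapply(mods, function(m) {
    rowSums(g$weights[, membership == m, drop = FALSE])
  }, numeric(n))
  P <- ifelse(s > 0, 1 - rowSums((sm / pmax(s, .Machine$double.eps))^2), 0)
  names(P) <- g$labels
  list(participation = P, hub_flag = P > threshold)
}
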