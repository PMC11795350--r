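#' Ring-lattice reference graph
#'
#' Builds the unit-weight ring lattice used as the reference for the
#' small-world ratios: each of the `n_nodes` nodes is connected to its
#' `k = floor(n_edges / n_nodes)` nearest neighbours per side, and the
#' remaining `n_edges mod n_nodes` edges are placed at the next neighbour
#' distance, assigned by ascending node index.
#'
#' @param n_nodes number of nodes (default 30).
#' @param n_edges number of edges; must be achievable on the ring lattice
#'   (at most `n_nodes * (n_nodes - 1) / 2`).
#' @return A `thresholded_graph` with unit weights.
#' @examples
#' g <- lattice_reference(30, 60)   # k = 2 ring: every degree 4
#' table(rowSums(g$weights))
#' @export
lattice_reference <- function(n_nodes = 30, n_edges) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    stop("n_edges exceeds the ", max_edges, " pairs of a ", n_nodes,
         "-node graph")
  }
  if (n_edges < 0) stop("n_edges must be non-negative")
  k <- n_edges %/% n_nodes
  rem <- n_edges %% n_nodes
  if (k > n_nodes %/% 2) stop("edge count not achievable on a ring lattice")
  w <- matrix(0, n_nodes, n_nodes)
  add_edge <- function(i, d) {
    j <- (i - 1 + d) %% n_nodes + 1
    w[i, j] <<- 1; w[j, i] <<- 1
  }
  if (k > 0) {
    for (d in 1:k) for (i in 1:n_nodes) add_edge(i, d)
  }
  # at distance n/2 (even n) each edge is shared by two nodes; guard below
  if (rem > 0) {
    placed <- 0
    for (i in 1:n_nodes) {
      j <- (i - 1 + k + 1) %% n_nodes + 1
      if (w[i, j] == 0) {
        w[i, j] <- 1; w[j, i] <- 1
        placed <- placed + 1
        if (placed == rem) break
      }
    }
    if (placed < rem) stop("edge count not achievable on a ring lattice")
  }
  labels <- paste0("L", seq_len(n_nodes))
  dimnames(w) <- list(labels, labels)
  g <- as_thresholded_graph(w)
  stopifnot(g$retained_edges == n_edges)
  g
}

# internal: binarize a thresholded graph (unit weights on retained edges)
binarize_graph <- function(g) {
  w <- named_weights(g)
  as_thresholded_graph((w != 0) * 1)
}

#' Small-world ratios against a reference graph
#'
#' Computes characteristic path length `L` and mean clustering `C` on the
#' binarized participant graph (unit weights on retained edges, so the
#' values are commensurate with a unit-weight reference) and the same
#' quantities `L_rand`, `C_rand` on the reference graph, then the ratios.
#'
#' Two conventions are offered. The default, `"as_printed"`, uses a ring
#' lattice reference ([lattice_reference()]) and defines
#' `gamma = L / L_rand`, `lambda = C / C_rand`, `sigma = gamma / lambda`.
#' The `"watts_strogatz"` convention uses the customary definitions
#' `gamma = C / C_rand`, `lambda = L / L_rand` against a degree-preserving
#' randomized reference (seeded edge rewiring, `n_rand` realizations
#' averaged). Both label their convention in the result.
#'
#' @param g a `thresholded_graph`.
#' @param reference reference graph (a `thresholded_graph`); when `NULL`,
#'   built automatically: a ring lattice with the same node and edge count
#'   (`as_printed`) or a rewired ensemble (`watts_strogatz`). If supplied,
#'   it must match the binarized graph's node and edge counts.
#' @param convention `"as_printed"` or `"watts_strogatz"`.
#' @param seed seed for the rewiring ensemble.
#' @param n_rand rewired realizations to average (watts_strogatz only).
#' @return An object of class `small_world_result`: list with `L`, `C`,
#'   `L_rand`, `C_rand`, `gamma`, `lambda`, `sigma`, `convention`,
#'   `disconnected`.
#' @export
small_world <- function(g, reference = NULL,
                        convention = c("as_printed", "watts_strogatz"),
                        seed = 1, n_rand = 10) {
  convention <- match.arg(convention)
  stopifnot(inherits(g, "thresholded_graph"))
  gb <- binarize_graph(g)
  n <- nrow(gb$weights)
  m <- gb$retained_edges
  pm <- path_metrics(gb)
  cl <- clustering_onnela(gb)

  if (convention == "as_printed") {
    if (is.null(reference)) reference <- lattice_reference(n, m)
    stopifnot(inherits(reference, "thresholded_graph"))
    rb <- binarize_graph(reference)
    if (nrow(rb$weights) != n || rb$retained_edges != m) {
      stop("reference must match the graph's node count (", n,
           ") and edge count (", m, ")")
    }
    pr <- path_metrics(rb)
    cr <- clustering_onnela(rb)
    L_rand <- pr$L; C_rand <- cr$C
    gamma <- pm$L / L_rand
    lambda <- cl$C / C_rand
  } else {
    if (!is.null(reference)) {
      stopifnot(inherits(reference, "thresholded_graph"))
      rb <- binarize_graph(reference)
      if (nrow(rb$weights) != n || rb$retained_edges != m) {
        stop("reference must match the graph's node count (", n,
             ") and edge count (", m, ")")
      }
      pr <- path_metrics(rb)
      cr <- clustering_onnela(rb)
      L_rand <- pr$L; C_rand <- cr$C
    } else {
      ig <- igraph::graph_from_adjacency_matrix(named_weights(gb),
                                                mode = "undirected",
                                                diag = FALSE)
      set.seed(seed)
      Ls <- Cs <- numeric(n_rand)
      for (r in seq_len(n_rand)) {
        rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * m))
        wj <- igraph::as_adjacency_matrix(rw, sparse = FALSE)
        gj <- as_thresholded_graph(wj)
        Ls[r] <- path_metrics(gj)$L
        Cs[r] <- clustering_onnela(gj)$C
      }
      L_rand <- mean(Ls); C_rand <- mean(Cs)
    }
    gamma <- cl$C / C_rand
    lambda <- pm$L / L_rand
  }
  sigma <- gamma / lambda
  structure(list(L = pm$L, C = cl$C, L_rand = L_rand, C_rand = C_rand,
                 gamma = gamma, lambda = lambda, sigma = sigma,
                 convention = convention, disconnected = pm$disconnected),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("small_world_result (%s): L=%.4f C=%.4f L_rand=%.4f C_rand=%.4f\n",
              x$convention, x$L, x$C, x$L_rand, x$C_rand))
  cat(sprintf("  gamma=%.4f lambda=%.4f sigma=%.4f%s\n", x$gamma, x$lambda,
              x$sigma, if (x$disconnected) " [disconnected]" else ""))
  invisible(x)
}
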