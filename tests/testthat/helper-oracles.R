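# Independent brute-force oracles for the graph metrics. These deliberately
# avoid igraph and the package's own implementations: Floyd-Warshall for
# distances, exhaustive simple-path enumeration for betweenness, and a
# triple loop for weighted clustering.

rand_wgraph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
  }
  w
}

oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_L_Eglob <- function(w) {
  d <- oracle_distances(w)
  off <- d[upper.tri(d)]
  fin <- is.finite(off)
  list(L = mean(off[fin]), E_glob = mean(ifelse(fin, 1 / off, 0)),
       disconnected = !all(fin))
}

# all simple paths between a and b with their costs (distances 1/w)
enum_paths <- function(w, a, b) {
  n <- nrow(w)
  out <- list()
  walk <- function(node, visited, cost, path) {
    if (node == b) {
      out[[length(out) + 1]] <<- list(cost = cost, path = path)
      return(invisible())
    }
    for (nxt in which(w[node, ] > 0)) {
      if (!visited[nxt]) {
        visited[nxt] <- TRUE
        walk(nxt, visited, cost + 1 / w[node, nxt], c(path, nxt))
        visited[nxt] <- FALSE
      }
    }
  }
  v <- rep(FALSE, n); v[a] <- TRUE
  walk(a, v, 0, a)
  out
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  bc <- numeric(n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    paths <- enum_paths(w, a, b)
    if (!length(paths)) next
    costs <- vapply(paths, `[[`, 0, "cost")
    best <- min(costs)
    shortest <- paths[abs(costs - best) < 1e-12]
    through <- table(unlist(lapply(shortest, function(p) {
      inner <- setdiff(p$path, c(a, b))
      unique(inner)
    })))
    for (v in names(through)) {
      bc[as.integer(v)] <- bc[as.integer(v)] +
        through[[v]] / length(shortest)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(list(cc = numeric(n), C = 0))
  wh <- w / mx
  cc <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h) {
        s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    cc[i] <- s / (k * (k - 1))
  }
  list(cc = cc, C = mean(cc))
}
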