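# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where practical, the libraries) used by the
# implementation: Floyd-Warshall distances, explicit shortest-path
# enumeration for betweenness, dense eigendecomposition for eigenvector
# centrality, a linear solve for PageRank.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all shortest paths between s and t by depth-first enumeration
.enumerate_paths <- function(adj, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) { paths[[length(paths) + 1L]] <<- acc; return(invisible()) }
    for (u in which(adj[v, ] == 1))
      if (D[v, t] == D[u, t] + 1) walk(u, c(acc, u))
  }
  walk(s, s)
  paths
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- .enumerate_paths(adj, D, s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      b[inner] <- b[inner] + 1 / length(paths)
    }
  }
  b
}

oracle_components <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  memb <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) if (memb[i] == 0L) {
    cur <- cur + 1L
    memb[is.finite(D[i, ])] <- cur
  }
  memb
}

oracle_eigencentrality <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  memb <- oracle_components(adj)
  for (ci in unique(memb)) {
    idx <- which(memb == ci)
    if (length(idx) < 2L) next
    ev <- eigen(adj[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- ev$vectors[, which.max(ev$values)]
    out[idx] <- abs(v) / sqrt(sum(v^2))
  }
  out
}

oracle_pagerank <- function(adj, d = 0.85) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  # column-stochastic transition with dangling columns = 1/n
  M <- matrix(0, n, n)
  for (j in seq_len(n))
    M[, j] <- if (deg[j] > 0) adj[, j] / deg[j] else 1 / n
  solve(diag(n) - d * M, rep((1 - d) / n, n))
}

oracle_local_metrics <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  deg <- rowSums(adj)
  clust <- numeric(n); localeff <- numeric(n)
  closeness <- numeric(n); harm <- numeric(n); ecc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k >= 2) {
      sub <- adj[nb, nb, drop = FALSE]
      clust[i] <- sum(sub) / (k * (k - 1))
      Ds <- oracle_distances(sub)
      inv <- 1 / Ds; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
      localeff[i] <- sum(inv) / (k * (k - 1))
    }
    di <- D[i, -i]
    fin <- is.finite(di) & di > 0
    if (any(fin)) {
      closeness[i] <- sum(fin) / sum(di[fin])
      harm[i] <- sum(1 / di[fin])
      ecc[i] <- max(di[fin])
    }
  }
  data.frame(degree = deg, clustering = clust, localeff = localeff,
             eigencentrality = oracle_eigencentrality(adj),
             closeness = closeness, betweenness = oracle_betweenness(adj),
             harmonic = harm, eccentricity = ecc,
             pagerank = oracle_pagerank(adj))
}

oracle_global_metrics <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(c(density = 0, efficiency = 0, assortativity = 0))
  m <- sum(adj) / 2
  D <- oracle_distances(adj)
  inv <- 1 / D; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  # assortativity: Pearson correlation of end degrees over directed edges
  deg <- rowSums(adj)
  es <- which(adj == 1, arr.ind = TRUE)   # both directions
  a <- if (m == 0) NaN else suppressWarnings(cor(deg[es[, 1]], deg[es[, 2]]))
  if (!is.finite(a)) a <- 0
  c(density = 2 * m / (n * (n - 1)), efficiency = sum(inv) / (n * (n - 1)),
    assortativity = a)
}

random_adj <- function(n, p_edge) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- rbinom(length(up), 1, p_edge)
  adj + t(adj)
}

adj_to_igraph_pattern <- function(adj) {
  # place points so that build_graph reproduces an arbitrary adjacency:
  # instead, construct the igraph directly
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# literal K estimator on small n (independent double loop in R)
oracle_ripley <- function(pattern, radii) {
  n <- pattern$n_cells
  a <- pattern$frame_um[1]; b <- pattern$frame_um[2]
  W <- pattern$area_mm2 * 1e6
  K <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(pattern$x_um[i] - pattern$x_um[j])
      dy <- abs(pattern$y_um[i] - pattern$y_um[j])
      if (sqrt(dx^2 + dy^2) <= radii[ri])
        s <- s + (a * b) / ((a - dx) * (b - dy))
    }
    K[ri] <- W / n^2 * s
  }
  K
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
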