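# Proximity-graph topology features.
#
# Each Ki-67-positive cell is a node; two nodes are connected when their
# Euclidean distance does not exceed the proximity threshold (closed
# inequality). Three thresholds -- 25, 50 and 75 um -- model contiguity at
# different scales. Per graph: 9 local (per-node) metrics, each summarised
# by 16 statistical indices, plus 3 global metrics = 147 features; over the
# three thresholds, 441.

GRAPH_THRESHOLDS_UM <- c(25, 50, 75)
LOCAL_METRICS <- c("degree", "clustering", "localeff", "eigencentrality",
                   "closeness", "betweenness", "harmonic", "eccentricity",
                   "pagerank")
GLOBAL_METRICS <- c("density", "efficiency", "assortativity")
SUMMARY_STATS <- c("mean", "gmean", "hmean", "sd", "skewness", "kurtosis",
                   "range", "mode", "min", "max", "q1", "q2", "q3",
                   "m2", "m3", "m4")

#' Build the proximity graph of a cell pattern
#'
#' @param pattern `cell_pattern`.
#' @param threshold_um connection radius in micrometres; an edge joins two
#'   cells iff their distance is `<= threshold_um`.
#' @return `igraph` undirected graph with vertex count `n_cells`; the
#'   threshold is stored in the graph attribute `threshold_um`.
#' @export
build_graph <- function(pattern, threshold_um) {
  n <- pattern$n_cells
  if (n == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- cpp_edge_list(pattern$x_um, pattern$y_um, threshold_um)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges) > 0)
      g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g <- igraph::set_graph_attr(g, "threshold_um", threshold_um)
  g
}

# eigenvector centrality per connected component: power iteration on each
# component's adjacency (+I shift), tolerance 1e-13, L2-normalised within
# component.
# Single-node components get 0.
.eigencentrality_components <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) < 2L) next
    Ac <- A[idx, idx, drop = FALSE]
    v <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in 1:10000) {
      # shift by +I: same principal eigenvector, avoids oscillation on
      # bipartite components
      v2 <- as.numeric(Ac %*% v) + v
      nv <- sqrt(sum(v2^2))
      if (nv == 0) { v <- v2; break }
      v2 <- v2 / nv
      if (max(abs(v2 - v)) < 1e-13) { v <- v2; break }
      v <- v2
    }
    out[idx] <- abs(v)
  }
  out
}

# PageRank by power iteration, damping d; dangling mass redistributed
# uniformly. Deterministic to tolerance 1e-12.
.pagerank_power <- function(g, d = 0.85) {
  n <- igraph::vcount(g)
  if (n == 0L) return(numeric(0))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- igraph::degree(g)
  x <- rep(1 / n, n)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  for (it in 1:10000) {
    contrib <- as.numeric(A %*% (x * inv))
    dangling <- sum(x[deg == 0])
    x2 <- (1 - d) / n + d * (contrib + dangling / n)
    if (max(abs(x2 - x)) < 1e-12) { x <- x2; break }
    x <- x2
  }
  x
}

# local efficiency: global efficiency of the subgraph induced by each
# node's neighbours (node itself removed); < 2 neighbours gives 0.
.local_efficiency <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  for (i in seq_len(n)) {
    nb <- as.integer(adj[[i]])
    nb <- setdiff(nb, i)
    k <- length(nb)
    if (k < 2L) next
    sub <- igraph::induced_subgraph(g, nb)
    dsub <- igraph::distances(sub)
    invd <- 1 / dsub
    diag(invd) <- 0
    invd[!is.finite(invd)] <- 0
    out[i] <- sum(invd) / (k * (k - 1))
  }
  out
}

#' Local (per-node) graph metrics
#'
#' Nine single-node descriptors: degree, clustering coefficient, local
#' efficiency, eigenvector centrality (per connected component), closeness
#' (within reachable set: reachable count over summed distances), unweighted
#' betweenness, harmonic centrality, eccentricity (within component) and
#' PageRank (damping 0.85). Isolated nodes get 0 everywhere except PageRank.
#'
#' @param graph an `igraph` graph from [build_graph()].
#' @return data.frame with one row per node and one column per metric.
#' @export
local_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(LOCAL_METRICS)))
    names(out) <- LOCAL_METRICS
    return(out)
  }
  D <- igraph::distances(graph)
  fin <- is.finite(D) & D > 0
  Dz <- D; Dz[!fin] <- 0
  sumd <- rowSums(Dz)
  reach <- rowSums(fin)
  closeness <- ifelse(sumd > 0, reach / sumd, 0)
  harm <- rowSums(ifelse(fin, 1 / D, 0))
  ecc <- apply(D, 1, function(r) { r <- r[is.finite(r)]; max(r) })
  clust <- igraph::transitivity(graph, type = "local", isolates = "zero")
  clust[is.na(clust)] <- 0
  data.frame(
    degree = as.numeric(igraph::degree(graph)),
    clustering = clust,
    localeff = .local_efficiency(graph),
    eigencentrality = .eigencentrality_components(graph),
    closeness = closeness,
    betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
    harmonic = harm,
    eccentricity = as.numeric(ecc),
    pagerank = .pagerank_power(graph)
  )
}

#' Global graph metrics
#'
#' Edge density, global efficiency (mean inverse shortest-path distance over
#' ordered pairs, 0 for unreachable pairs) and degree assortativity
#' (Pearson correlation of degrees over edge endpoints; 0 by convention when
#' undefined, e.g. regular graphs). Graphs with fewer than 2 nodes give all
#' zeros.
#'
#' @param graph an `igraph` graph.
#' @return named numeric vector of length 3.
#' @export
global_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L)
    return(c(density = 0, efficiency = 0, assortativity = 0))
  m <- igraph::ecount(graph)
  density <- 2 * m / (n * (n - 1))
  D <- igraph::distances(graph)
  invd <- 1 / D
  diag(invd) <- 0
  invd[!is.finite(invd)] <- 0
  eff <- sum(invd) / (n * (n - 1))
  assort <- if (m == 0) NaN else
    suppressWarnings(igraph::assortativity_degree(graph, directed = FALSE))
  if (!is.finite(assort)) assort <- 0
  c(density = density, efficiency = eff, assortativity = assort)
}

#' The 16 summary statistics of a value list
#'
#' Fixed order: arithmetic, geometric and harmonic mean, standard deviation
#' (sample, n-1), skewness (standardised third moment), excess kurtosis,
#' range, mode, min, max, quartiles Q1-Q3 (linear interpolation, inclusive;
#' R quantile type 7), and the 2nd/3rd/4th central moments (population, /n).
#'
#' Conventions: a list containing a non-positive value has geometric and
#' harmonic mean 0; a constant list has skewness and kurtosis 0; the mode of
#' continuous values is the most frequent value after rounding to 9
#' significant digits, ties resolved to the smallest value. An empty list
#' returns 16 zeros with a warning.
#'
#' @param values numeric vector.
#' @return named numeric vector of length 16.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L) {
    warning("empty value list; summary statistics set to 0")
    return(stats::setNames(numeric(length(SUMMARY_STATS)), SUMMARY_STATS))
  }
  n <- length(values)
  m <- mean(values)
  gm <- if (any(values <= 0)) 0 else exp(mean(log(values)))
  hm <- if (any(values <= 0)) 0 else 1 / mean(1 / values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  s <- if (n > 1) sqrt(m2 * n / (n - 1)) else 0
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  rv <- signif(values, 9)
  tab <- table(rv)
  best <- names(tab)[tab == max(tab)]
  mode_v <- min(as.numeric(best))
  out <- c(m, gm, hm, s, skew, kurt, max(values) - min(values), mode_v,
           min(values), max(values), q[1], q[2], q[3], m2, m3, m4)
  stats::setNames(out, SUMMARY_STATS)
}

#' The 441-feature graph block of a pattern
#'
#' For each proximity threshold (25, 50, 75 um): 9 local metrics x 16
#' summary statistics + 3 global metrics = 147 features, named
#' `g{threshold}_{metric}_{stat}` and `g{threshold}_{global}`.
#'
#' @param pattern `cell_pattern`.
#' @param thresholds_um connection radii (default 25/50/75).
#' @return named numeric vector of length 441.
#' @export
graph_feature_block <- function(pattern, thresholds_um = GRAPH_THRESHOLDS_UM) {
  if (pattern$n_cells == 0L)
    warning("empty pattern; graph features set to 0")
  out <- numeric(0)
  for (t in thresholds_um) {
    g <- build_graph(pattern, t)
    lm <- if (pattern$n_cells == 0L) NULL else local_metrics(g)
    for (metric in LOCAL_METRICS) {
      v <- if (is.null(lm)) numeric(0) else lm[[metric]]
      s <- suppressWarnings(summarize_values(v))
      names(s) <- sprintf("g%d_%s_%s", t, metric, SUMMARY_STATS)
      out <- c(out, s)
    }
    gl <- global_metrics(g)
    names(gl) <- sprintf("g%d_%s", t, GLOBAL_METRICS)
    out <- c(out, gl)
  }
  out
}

#' Display transform for eigenvector centrality maps
#'
#' `c' = log2(c) - min(log2(c))`, so the minimum of the output is 0. All
#' inputs must be positive; when plotting per-component centralities,
#' assign isolated nodes the smallest positive value first.
#'
#' @param values positive numeric vector.
#' @return transformed vector.
#' @export
eigcentrality_display_transform <- function(values) {
  if (any(values <= 0)) stop("all centrality values must be positive")
  l <- log2(values)
  l - min(l)
}
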