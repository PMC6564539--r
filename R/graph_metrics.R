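# Binary undirected graph metrics, GAT/Rubinov-Sporns conventions.
# Heavy lifting is in the C++ kernels (src/metrics.cpp); these wrappers
# validate input and fix the conventions: nodes of degree < 2 contribute 0
# to clustering and local efficiency, path length is defined only on
# connected graphs, betweenness is the unnormalized pair-fraction sum.

check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  if (any(adj != 0 & adj != 1)) stop("adjacency must be binary")
  if (any(adj != t(adj))) stop("adjacency must be symmetric (undirected)")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero (no self-loops)")
  storage.mode(adj) <- "integer"
  adj
}

#' Mean clustering coefficient
#'
#' Average over nodes of the fraction of a node's neighbor pairs that are
#' themselves connected; nodes with fewer than two neighbors contribute 0.
#'
#' @param adj Binary symmetric adjacency matrix, zero diagonal.
#' @param nodal Return the per-node vector instead of the mean.
#' @return Scalar in `[0, 1]`, or a per-node vector when `nodal = TRUE`.
#' @export
clustering_coefficient <- function(adj, nodal = FALSE) {
  adj <- check_adjacency(adj)
  ci <- cpp_triangle_stats(adj)$local
  if (nodal) setNames(ci, rownames(adj)) else mean(ci)
}

#' Transitivity
#'
#' `3 * triangles / connected triples`: the whole-graph variant of the
#' clustering coefficient, less influenced by low-degree nodes. 0 when the
#' graph has no connected triples.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
transitivity <- function(adj) {
  adj <- check_adjacency(adj)
  cpp_triangle_stats(adj)$transitivity
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (mean inverse shortest-path length within the neighborhood);
#' nodes with fewer than two neighbors contribute 0. Returned as the mean
#' over nodes unless `nodal = TRUE`.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`, or a per-node vector.
#' @export
local_efficiency <- function(adj, nodal = FALSE) {
  adj <- check_adjacency(adj)
  e <- as.numeric(cpp_local_efficiency(adj))
  if (nodal) setNames(e, rownames(adj)) else mean(e)
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over all node pairs; unreachable
#' pairs contribute 0, so fragmentation is allowed.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  adj <- check_adjacency(adj)
  unname(cpp_global_metrics(adj)["global_efficiency"])
}

#' Characteristic path length
#'
#' Mean shortest-path length over all node pairs of a connected graph.
#' Errors on a fragmented graph (unreachable pairs make the mean
#' undefined); in the pipeline the minimum-density search guarantees
#' connectedness.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar >= 1 for non-trivial connected graphs.
#' @export
characteristic_path_length <- function(adj) {
  adj <- check_adjacency(adj)
  m <- cpp_global_metrics(adj)
  if (m["n_components"] > 1)
    stop("graph is fragmented (", m["n_components"],
         " components); characteristic path length is undefined")
  unname(m["path_length"])
}

#' Node betweenness centrality
#'
#' Unnormalized Brandes betweenness: for each node, the sum over node pairs
#' of the fraction of shortest paths passing through it (endpoints
#' excluded).
#'
#' @inheritParams clustering_coefficient
#' @return Named per-node vector.
#' @export
node_betweenness <- function(adj) {
  adj <- check_adjacency(adj)
  setNames(as.numeric(cpp_betweenness(adj)), rownames(adj))
}

#' Node degree
#' @inheritParams clustering_coefficient
#' @return Named integer vector of node degrees.
#' @export
node_degree <- function(adj) {
  adj <- check_adjacency(adj)
  setNames(as.integer(rowSums(adj)), rownames(adj))
}

#' All global metrics of one binary graph
#'
#' @inheritParams clustering_coefficient
#' @return Named list: `clustering`, `transitivity`, `local_efficiency`,
#'   `global_efficiency`, `path_length` (NA if fragmented),
#'   `n_components`.
#' @export
graph_metrics <- function(adj) {
  adj <- check_adjacency(adj)
  as.list(cpp_global_metrics(adj))
}

#' Newman modularity of a given partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]`: intra-module edge fraction minus
#' the expectation under the degree-preserving random model.
#'
#' @inheritParams clustering_coefficient
#' @param membership Integer community label per node.
#' @return Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(adj, membership) {
  adj <- check_adjacency(adj)
  stopifnot(length(membership) == nrow(adj))
  m2 <- sum(adj)              # 2m
  if (m2 == 0) stop("graph has no edges")
  q <- 0
  for (cmty in unique(membership)) {
    v <- membership == cmty
    e_c <- sum(adj[v, v, drop = FALSE])        # 2 * intra edges
    d_c <- sum(adj[v, , drop = FALSE])         # total degree in community
    q <- q + e_c / m2 - (d_c / m2)^2
  }
  q
}

#' Louvain community detection with max-Q restarts
#'
#' Runs the Louvain algorithm (via igraph) `restarts` times under distinct
#' seeds and keeps the partition with the highest modularity Q, recomputed
#' by [modularity_q()]. Reproducible bit-for-bit for a given seed and
#' restart count.
#'
#' @inheritParams clustering_coefficient
#' @param seed Integer seed.
#' @param restarts Number of independent Louvain runs.
#' @return List: `Q` (max over restarts), `membership` (named integer
#'   vector, labels 1..k by decreasing module size), `n_modules`,
#'   `q_values` (per restart).
#' @export
modularity_louvain <- function(adj, seed = 1L, restarts = 20L) {
  adj <- check_adjacency(adj)
  if (sum(adj) == 0) stop("graph has no edges; modularity undefined")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  best_q <- -Inf
  best_mem <- NULL
  qv <- numeric(restarts)
  for (b in seq_len(restarts)) {
    set.seed(seed + b - 1L)
    mem <- as.integer(igraph::membership(igraph::cluster_louvain(g)))
    qv[b] <- modularity_q(adj, mem)
    if (qv[b] > best_q) { best_q <- qv[b]; best_mem <- mem }
  }
  # stable labels: 1..k by decreasing module size (ties by first node)
  sizes <- table(best_mem)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  relabel <- match(best_mem, as.integer(names(sizes))[ord])
  list(Q = best_q,
       membership = setNames(relabel, rownames(adj)),
       n_modules = length(sizes), q_values = qv)
}

#' Degree-preserving null network
#'
#' Maslov-Sneppen double-edge-swap rewiring: random edge pairs are rewired
#' (rejecting self-loops and multi-edges) so the degree sequence is exactly
#' preserved while all other structure is randomized. The swap target is
#' `swap_factor` times the edge count.
#'
#' @inheritParams clustering_coefficient
#' @param seed Optional integer seed (`set.seed` is called when given;
#'   otherwise the current RNG stream is used).
#' @param swap_factor Successful swaps per edge (default 10).
#' @return Binary adjacency with the same degree sequence. If no legal
#'   swap exists the input is returned with a warning.
#' @export
null_network <- function(adj, seed = NULL, swap_factor = 10) {
  adj <- check_adjacency(adj)
  ne <- sum(adj) / 2
  if (ne < 2) {
    warning("fewer than 2 edges; returning the input graph")
    return(adj)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_rewire(adj, as.integer(round(swap_factor * ne)))
  if (out$n_swaps == 0) {
    warning("no legal degree-preserving swap exists; returning the input graph")
    return(adj)
  }
  res <- out$adjacency
  dimnames(res) <- dimnames(adj)
  res
}

#' Small-worldness against degree-preserving nulls
#'
#' `gamma = C / <C_null>` and `lambda = L / <L_null>` over `n_null`
#' rewired null networks ([null_network()]); `sigma = gamma / lambda`.
#' Values of sigma above 1 are read as small-world topology. Null path
#' lengths are averaged over reachable pairs, so an occasional fragmented
#' null does not break the normalization.
#'
#' @inheritParams clustering_coefficient
#' @param n_null Number of null networks (default 20).
#' @param seed Integer seed; nulls are drawn from one seeded stream.
#' @param swap_factor Passed to [null_network()].
#' @return List: `sigma`, `gamma`, `lambda`, `C`, `L`, and the per-null
#'   `C_null`, `L_null` vectors. `sigma` is NA (with a message) if the
#'   null clustering averages to zero.
#' @export
small_worldness <- function(adj, n_null = 20L, seed = 1L, swap_factor = 10) {
  adj <- check_adjacency(adj)
  m <- cpp_global_metrics(adj)
  if (m["n_components"] > 1)
    stop("graph is fragmented; small-worldness needs a connected graph")
  C <- unname(m["clustering"])
  L <- unname(m["path_length"])
  set.seed(seed)
  c_null <- l_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nb <- null_network(adj, seed = NULL, swap_factor = swap_factor)
    mb <- cpp_global_metrics(nb)
    c_null[b] <- mb["clustering"]
    l_null[b] <- if (mb["n_components"] == 1) mb["path_length"]
                 else mean_finite_distance(nb)
  }
  gamma <- if (mean(c_null) > 0) C / mean(c_null) else NA_real_
  lambda <- L / mean(l_null)
  sigma <- if (is.na(gamma)) { message("null clustering is zero; sigma undefined"); NA_real_ }
           else gamma / lambda
  list(sigma = sigma, gamma = gamma, lambda = lambda, C = C, L = L,
       C_null = c_null, L_null = l_null)
}

# mean shortest-path length over reachable pairs only
mean_finite_distance <- function(adj) {
  D <- cpp_all_pairs_dist(adj)
  d <- D[D > 0]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Identify hubs by the mean + k*SD rule
#'
#' A node is a hub when its statistic is at least `sd_multiplier` sample
#' standard deviations above the cross-node mean. A constant statistic
#' yields no hubs.
#'
#' @param stat Named numeric vector of a node statistic (betweenness,
#'   degree, or their density-integrated versions).
#' @param sd_multiplier Threshold multiplier (default 2).
#' @return List of class `"scn_hubs"`: `hubs` (names, or indices when
#'   unnamed), `threshold`, `mean`, `sd`, `sd_multiplier`.
#' @export
identify_hubs <- function(stat, sd_multiplier = 2) {
  stopifnot(length(stat) >= 2)
  mu <- mean(stat); s <- sd(stat)
  thr <- mu + sd_multiplier * s
  idx <- if (s == 0) integer(0) else which(stat >= thr)
  hubs <- if (!is.null(names(stat))) names(stat)[idx] else idx
  out <- list(hubs = hubs, threshold = thr, mean = mu, sd = s,
              sd_multiplier = sd_multiplier)
  class(out) <- "scn_hubs"
  out
}

#' @export
print.scn_hubs <- function(x, ...) {
  cat(sprintf("hubs (stat >= mean + %g SD = %.4g): %s\n", x$sd_multiplier,
              x$threshold,
              if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none"))
  invisible(x)
}
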