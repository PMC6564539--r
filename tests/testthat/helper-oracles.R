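# Brute-force reference implementations used as independent oracles.
# All operate on dense adjacency matrices and use only base R, with
# algorithms different from the package kernels (Floyd-Warshall instead of
# BFS, matrix-power path counting instead of Brandes accumulation,
# exhaustive pair loops instead of incremental sweeps).

# Floyd-Warshall all-pairs distances; Inf for unreachable
o_dist <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

o_clustering_local <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        links <- links + adj[nb[a], nb[b]]
    2 * links / (k * (k - 1))
  }, numeric(1))
}

o_clustering <- function(adj) mean(o_clustering_local(adj))

o_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0; triples <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    triples <- triples + k * (k - 1) / 2
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        tri <- tri + adj[nb[a], nb[b]]
  }
  if (triples == 0) 0 else tri / triples  # tri counts each triangle 3x
}

o_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- o_dist(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

o_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    o_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

o_path_length <- function(adj) {
  n <- nrow(adj)
  D <- o_dist(adj)
  offd <- D[row(D) != col(D)]
  if (any(!is.finite(offd))) return(NA_real_)
  mean(offd)
}

# betweenness by shortest-path counting with adjacency-matrix powers:
# the number of shortest s-t paths through v is N[d(s,v)][s,v] *
# N[d(v,t)][v,t] when d(s,v) + d(v,t) = d(s,t)
o_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- o_dist(adj)
  maxd <- max(D[is.finite(D)])
  powers <- vector("list", max(maxd, 1))
  P <- diag(n)
  for (d in seq_len(max(maxd, 1))) {
    P <- P %*% adj
    powers[[d]] <- P
  }
  count <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d) || d == 0) return(if (s == t) 1 else 0)
    powers[[d]][s, t]
  }
  b <- numeric(n)
  for (s in seq_len(n - 1))
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      sigma_st <- count(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          b[v] <- b[v] + count(s, v) * count(v, t) / sigma_st
      }
    }
  b
}

o_n_components <- function(adj) {
  D <- o_dist(adj)
  length(unique(apply(is.finite(D), 1, function(r) paste(which(r), collapse = ","))))
}

o_modularity <- function(adj, mem) {
  m2 <- sum(adj)
  q <- 0
  for (cmty in unique(mem)) {
    v <- mem == cmty
    q <- q + sum(adj[v, v]) / m2 - (sum(adj[v, ]) / m2)^2
  }
  q
}

# Erdos-Renyi random adjacency with fixed seed
rand_adj <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# named small graphs used across tests
graph_k3 <- function() {
  a <- matrix(1L, 3, 3); diag(a) <- 0L; a
}
graph_p3 <- function() rbind(c(0L,1L,0L), c(1L,0L,1L), c(0L,1L,0L))
graph_p4 <- function() {
  a <- matrix(0L, 4, 4)
  a[cbind(1:3, 2:4)] <- 1L
  a + t(a)
}
graph_chorded_c4 <- function() {
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- a[4, 1] <- a[1, 3] <- 1L
  a + t(a)
}
graph_star4 <- function() {
  a <- matrix(0L, 4, 4); a[1, 2:4] <- 1L; a + t(a)
}
graph_double_triangle <- function() {
  a <- matrix(0L, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- a[4, 5] <- a[5, 6] <- a[4, 6] <- a[3, 4] <- 1L
  a + t(a)
}
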