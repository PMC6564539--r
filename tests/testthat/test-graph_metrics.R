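# Graph metric kernels against closed forms, brute-force oracles and
# igraph cross-checks.

test_that("metrics agree with brute-force oracles on random graphs", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(5:12, 1)
    adj <- rand_adj(n, p = runif(1, 0.25, 0.6), seed = s)
    expect_equal(clustering_coefficient(adj), o_clustering(adj), tolerance = 1e-10)
    expect_equal(transitivity(adj), o_transitivity(adj), tolerance = 1e-10)
    expect_equal(local_efficiency(adj), o_local_efficiency(adj), tolerance = 1e-10)
    expect_equal(global_efficiency(adj), o_global_efficiency(adj), tolerance = 1e-10)
    expect_equal(unname(node_betweenness(adj)), o_betweenness(adj), tolerance = 1e-10)
    L <- o_path_length(adj)
    if (!is.na(L)) {
      expect_equal(characteristic_path_length(adj), L, tolerance = 1e-10)
    } else {
      expect_error(characteristic_path_length(adj), "fragmented")
    }
  }
})

test_that("closed forms on named small graphs are exact", {
  k3 <- graph_k3()
  expect_equal(clustering_coefficient(k3), 1)
  expect_equal(transitivity(k3), 1)
  expect_equal(local_efficiency(k3), 1)
  expect_equal(global_efficiency(k3), 1)
  expect_equal(characteristic_path_length(k3), 1)
  p3 <- graph_p3()
  expect_equal(clustering_coefficient(p3), 0)
  expect_equal(local_efficiency(p3), 0)
  expect_equal(characteristic_path_length(p3), 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(characteristic_path_length(graph_p4()), 10 / 6)
  ch <- graph_chorded_c4()
  expect_equal(clustering_coefficient(ch), 5 / 6)
  expect_equal(clustering_coefficient(ch, nodal = TRUE),
               c(2 / 3, 1, 2 / 3, 1), ignore_attr = TRUE)
  expect_equal(transitivity(ch), 3 / 4)
  star <- graph_star4()
  expect_equal(unname(node_betweenness(star)), c(3, 0, 0, 0))
  expect_equal(transitivity(star), 0)
  expect_equal(unname(node_betweenness(graph_k3())), c(0, 0, 0))
  expect_equal(global_efficiency(matrix(0L, 2, 2)), 0)
})

test_that("metric validation rejects malformed adjacency", {
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(clustering_coefficient(bad), "symmetric")
  expect_error(transitivity(diag(2)), "diagonal")
  expect_error(global_efficiency(matrix(2, 2, 2)), "binary")
})

test_that("efficiency and path length obey their joint inequalities", {
  for (s in 1:15) {
    adj <- rand_adj(10, p = 0.5, seed = s + 50)
    if (cpp_n_components(adj) != 1) next
    L <- characteristic_path_length(adj)
    expect_gte(global_efficiency(adj) + 1e-12, 1 / L)
    # adding an edge never increases L, never decreases E_glob
    miss <- which(upper.tri(adj) & adj == 0)
    if (!length(miss)) next
    adj2 <- adj
    adj2[miss[1]] <- 1L
    adj2 <- pmax(adj2, t(adj2))
    expect_lte(characteristic_path_length(adj2), L + 1e-12)
    expect_gte(global_efficiency(adj2) + 1e-12, global_efficiency(adj))
  }
})

test_that("modularity of a bridged double triangle is the hand value", {
  dt <- graph_double_triangle()
  ml <- modularity_louvain(dt, seed = 1, restarts = 10)
  expect_equal(ml$Q, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-10)  # 0.3571
  expect_equal(ml$n_modules, 2)
  expect_equal(unname(ml$membership[1:3]), rep(ml$membership[[1]], 3))
  # Q of the returned partition matches igraph's modularity
  g <- igraph::graph_from_adjacency_matrix(dt, mode = "undirected")
  expect_equal(ml$Q, igraph::modularity(g, ml$membership), tolerance = 1e-12)
})

test_that("modularity honours its contracts", {
  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  ml <- modularity_louvain(k5, seed = 2)
  expect_equal(ml$Q, 0, tolerance = 1e-10)  # complete graph: no structure
  expect_equal(ml$n_modules, 1)
  adj <- rand_adj(12, 0.3, seed = 9)
  ml2 <- modularity_louvain(adj, seed = 3)
  singletons <- modularity_q(adj, seq_len(12))
  expect_gte(ml2$Q, singletons)
  expect_equal(ml2$Q, o_modularity(adj, ml2$membership), tolerance = 1e-12)
  expect_error(modularity_louvain(matrix(0L, 3, 3)), "no edges")
  # bit-for-bit reproducibility under a fixed seed and restart schedule
  expect_identical(modularity_louvain(adj, seed = 7, restarts = 5),
                   modularity_louvain(adj, seed = 7, restarts = 5))
})

test_that("null networks preserve the degree sequence exactly", {
  for (s in 1:10) {
    adj <- rand_adj(20, 0.25, seed = s + 70)
    nn <- null_network(adj, seed = s)
    expect_identical(rowSums(nn), rowSums(adj))
    expect_equal(sum(nn), sum(adj))
    expect_true(all(diag(nn) == 0))
    expect_true(all(nn == t(nn)))
  }
  # rewiring really randomizes: some edge differs on a non-trivial graph
  adj <- rand_adj(20, 0.3, seed = 99)
  expect_true(any(null_network(adj, seed = 1) != adj))
})

test_that("null-network clustering matches the ER expectation", {
  # on ER graphs the degree-preserving null has clustering ~ edge density
  set.seed(42)
  adj <- rand_adj(20, 0.35, seed = 42)
  dens <- sum(adj) / (20 * 19)
  cc <- replicate(100, clustering_coefficient(null_network(adj)))
  expect_equal(mean(cc), dens, tolerance = 0.05)
})

test_that("a complete graph is its own null class", {
  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  sw <- suppressWarnings(small_worldness(k6, n_null = 5, seed = 1))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("hub rule: mean + 2 SD with sample SD, constant vectors give none", {
  x <- c(rep(0, 9), 20)
  h <- identify_hubs(x)
  expect_equal(h$threshold, mean(x) + 2 * sd(x))  # ~14.65
  expect_equal(h$hubs, 10L, ignore_attr = TRUE)
  h2 <- identify_hubs(c(1, 1, 1, 10))
  expect_equal(h2$threshold, 12.25)
  expect_length(h2$hubs, 0)
  expect_length(identify_hubs(rep(3, 8))$hubs, 0)
  named <- setNames(c(rep(0, 9), 50), letters[1:10])
  expect_equal(identify_hubs(named)$hubs, "j")
})
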