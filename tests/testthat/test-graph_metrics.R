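test_that("closed-form values on canonical small graphs", {
  # complete unit-weight K19: dense-graph identities
  W <- matrix(1, 19, 19); diag(W) <- 0
  g <- weighted_graph(W)
  # regular graph: endpoint strengths are constant, so assortativity
  # falls back to 0 with a warning
  m <- suppressWarnings(all_metrics(g, seed = 1))
  expect_equal(m$degree, 18)
  expect_equal(m$strength, 18)
  expect_equal(m$characteristic_path_length, 1)
  expect_equal(m$radius, 1)
  expect_equal(m$diameter, 1)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$transitivity, 1)
  # no community structure: the one-module partition (Q = 0) is optimal
  expect_true(m$modularity >= 0 - 1e-12 && m$modularity <= 1e-12)
  # complete graph cannot be rewired: sigma identically 1
  expect_identical(m$small_worldness, 1)

  # complete K4 with all weights 0.5
  W4 <- matrix(0.5, 4, 4); diag(W4) <- 0
  g4 <- weighted_graph(W4)
  expect_equal(degree_strength(g4)$strength, 1.5)
  # weights rescaled by max: clustering/local efficiency behave as K4
  expect_equal(clustering_transitivity(g4)$clustering_coefficient, 1)
  expect_equal(local_efficiency(weighted_graph(
    matrix(1, 4, 4) - diag(4))), 1)

  # 3-node chain with weights 0.5: d(A,C) = 1/0.5 + 1/0.5
  Wc <- matrix(0, 3, 3)
  Wc[1, 2] <- Wc[2, 1] <- 0.5
  Wc[2, 3] <- Wc[3, 2] <- 0.5
  expect_equal(distance_matrix(weighted_graph(Wc))[1, 3], 4)

  # unit star graph N=5: radius 1 (hub), diameter 2; no triangles
  Ws <- matrix(0, 5, 5)
  Ws[1, 2:5] <- Ws[2:5, 1] <- 1
  gs <- weighted_graph(Ws)
  pm <- path_measures(distance_matrix(gs))
  expect_equal(pm$radius, 1)
  expect_equal(pm$diameter, 2)
  ct <- clustering_transitivity(gs)
  expect_equal(ct$clustering_coefficient, 0)
  expect_equal(ct$transitivity, 0)
  expect_equal(local_efficiency(gs), 0)
  # hub-leaf anticorrelation
  expect_lt(assortativity_weighted(gs), 0)
})

test_that("regular ring has undefined assortativity, reported as 0", {
  n <- 8
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- 1
  }
  expect_warning(r <- assortativity_weighted(weighted_graph(W)),
                 "degenerate")
  expect_identical(r, 0)
})

test_that("deterministic measures match brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    W <- random_wgraph(n, density = runif(1, 0.4, 0.9))
    g <- weighted_graph(W)

    ds <- degree_strength(g)
    o <- oracle_degree_strength(W)
    expect_equal(ds$degree, o$degree, tolerance = 1e-12)
    expect_equal(ds$strength, o$strength, tolerance = 1e-12)

    d <- distance_matrix(g)
    expect_equal(d, oracle_distances(W), tolerance = 1e-12,
                 ignore_attr = TRUE)
    pm <- path_measures(d)
    po <- oracle_path_measures(oracle_distances(W))
    expect_equal(unlist(pm), unlist(po), tolerance = 1e-12)
    expect_lte(pm$radius, pm$diameter)

    ct <- clustering_transitivity(g)
    co <- oracle_clustering_transitivity(W)
    expect_equal(ct$clustering_coefficient, co$clustering_coefficient,
                 tolerance = 1e-12)
    expect_equal(ct$transitivity, co$transitivity, tolerance = 1e-12)

    expect_equal(local_efficiency(g), oracle_local_efficiency(W),
                 tolerance = 1e-12)
    expect_equal(assortativity_weighted(g), oracle_assortativity(W),
                 tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted modules and matches the partition oracle", {
  # two unit triangles joined by one weak bridge
  W <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    W[p[1], p[2]] <- W[p[2], p[1]] <- 1
  W[3, 4] <- W[4, 3] <- 0.1
  g <- weighted_graph(W)
  set.seed(7)
  lv <- louvain_modularity(g)
  ex <- oracle_best_q(W)
  expect_equal(lv$Q, ex$Q, tolerance = 1e-9)
  # the partition is the two triangles
  expect_equal(length(unique(lv$partition)), 2)
  expect_equal(length(unique(lv$partition[1:3])), 1)
  expect_equal(length(unique(lv$partition[4:6])), 1)
  # reported Q is the Q of the reported partition
  expect_equal(lv$Q, oracle_modularity_q(W, lv$partition),
               tolerance = 1e-12)

  # independent cross-check against igraph's Louvain on the same graph
  skip_if_not_installed("igraph")
  gi <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  cl <- igraph::cluster_louvain(gi)
  expect_equal(lv$Q, igraph::modularity(gi, igraph::membership(cl),
                                        weights = igraph::E(gi)$weight),
               tolerance = 1e-9)
})

test_that("weight-scale invariance and 1/k distance scaling hold", {
  set.seed(5)
  W <- random_wgraph(7, 0.7)
  g1 <- weighted_graph(W)
  g2 <- weighted_graph(3 * W)
  # scale-invariant: max-rescaled clustering, transitivity, modularity Q
  expect_equal(clustering_transitivity(g1), clustering_transitivity(g2),
               tolerance = 1e-12)
  memb <- rep(1:2, length.out = 7)
  expect_equal(oracle_modularity_q(W, memb),
               oracle_modularity_q(3 * W, memb), tolerance = 1e-12)
  # distances scale as 1/k, radius/diameter/CPL with them
  d1 <- distance_matrix(g1); d2 <- distance_matrix(g2)
  expect_equal(d2, d1 / 3, tolerance = 1e-12, ignore_attr = TRUE)
  p1 <- path_measures(d1); p2 <- path_measures(d2)
  expect_equal(p2$radius, p1$radius / 3, tolerance = 1e-12)
  expect_equal(p2$diameter, p1$diameter / 3, tolerance = 1e-12)
  expect_equal(p2$characteristic_path_length,
               p1$characteristic_path_length / 3, tolerance = 1e-12)
})

test_that("stochastic measures are reproducible under a fixed seed", {
  set.seed(10)
  W <- random_wgraph(8, 0.6)
  g <- weighted_graph(W)
  m1 <- all_metrics(g, seed = 123)
  m2 <- all_metrics(g, seed = 123)
  expect_identical(m1, m2)
})

test_that("small-worldness calibrates on random graphs and detects lattices", {
  # identity null: comparing a graph to itself gives exactly 1
  set.seed(3)
  W <- random_wgraph(8, 0.6)
  g <- weighted_graph(W)
  expect_identical(small_worldness(g, n_null = 1, rewires_per_edge = 0), 1)

  # Erdos-Renyi-like weighted graphs: sigma ~ 1 on average (the
  # single-graph ratio is noisy, so calibrate on the mean of 30)
  set.seed(31)
  s_er <- replicate(30, {
    Wr <- random_wgraph(20, 0.25)
    small_worldness(weighted_graph(Wr), n_null = 20)
  })
  expect_gt(mean(s_er), 0.85)
  expect_lt(mean(s_er), 1.15)

  # ring lattice with a few shortcuts: high clustering, short paths
  n <- 20
  Wl <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in 1:2) {
    j <- (i + k - 1) %% n + 1
    Wl[i, j] <- Wl[j, i] <- 1
  }
  set.seed(33)
  for (s in 1:3) {
    ij <- sample(n, 2)
    Wl[ij[1], ij[2]] <- Wl[ij[2], ij[1]] <- 1
  }
  set.seed(34)
  expect_gt(small_worldness(weighted_graph(Wl), n_null = 20), 1)
})

test_that("zero-weight and degenerate graphs are rejected", {
  W0 <- matrix(0, 4, 4)
  expect_error(louvain_modularity(weighted_graph(W0)), "zero-weight")
  expect_error(path_measures(matrix(0, 1, 1)), "2 nodes")
  expect_error(weighted_graph(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
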