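test_that("metrics reproduce closed forms on canonical small graphs", {
  p3 <- path_graph(3)
  expect_equal(unname(degree_centrality(p3)), c(1, 2, 1))
  expect_equal(shortest_paths(p3)[1, 3], 2)
  expect_equal(characteristic_path_length(p3), 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))

  k4 <- complete_graph(4)
  expect_equal(unname(degree_centrality(k4)), rep(3, 4))
  expect_equal(characteristic_path_length(k4), 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  expect_equal(clustering_coefficient(k4)$node, rep(1, 4))

  c5 <- cycle_graph(5)
  expect_equal(characteristic_path_length(c5), 1.5)

  st3 <- star_graph(3)   # center node 1
  ne <- nodal_efficiency(st3)
  expect_equal(unname(ne), c(1, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(clustering_coefficient(st3)$node, rep(0, 4))
  expect_equal(unname(local_efficiency(st3)), rep(0, 4))

  tri <- complete_graph(3)
  expect_equal(unname(local_efficiency(tri)), rep(1, 3))

  # K4 minus one edge: the two degree-3 nodes have C = 2/3
  k4m <- k4; k4m[1, 2] <- k4m[2, 1] <- 0L
  expect_equal(clustering_coefficient(k4m)$node[3:4], c(2 / 3, 2 / 3))
  expect_equal(clustering_coefficient(k4m)$node, oracle_clustering(k4m))

  # disconnected pair: infinite distance, efficiency contribution zero
  disc <- sym_adj(4, c(1, 2))
  expect_true(is.infinite(shortest_paths(disc)[1, 3]))
  expect_equal(global_efficiency(disc), 2 * 1 / (4 * 3))

  expect_equal(unname(degree_centrality(matrix(0L, 3, 3))), c(0, 0, 0))
})

test_that("adjacency validation rejects malformed graphs", {
  bad <- matrix(0L, 3, 3); bad[1, 2] <- 1L
  expect_error(degree_centrality(bad), "symmetric")
  loop <- matrix(0L, 2, 2); diag(loop) <- 1L
  expect_error(degree_centrality(loop), "diagonal")
  expect_error(degree_centrality(matrix(2L, 2, 2)), "binary")
})

test_that("engine equals brute-force oracles on random graphs", {
  for (s in 1:60) {
    n <- sample(6:10, 1)
    a <- random_graph(n, runif(1, 0.2, 0.7), 5000 + s)
    expect_equal(unname(shortest_paths(a)), oracle_distances(a))
    expect_equal(unname(betweenness_centrality(a)), oracle_betweenness(a),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(a)$node, oracle_clustering(a))
    expect_equal(unname(local_efficiency(a)), oracle_local_eff(a))
    expect_equal(unname(nodal_efficiency(a)), oracle_nodal_eff(a))
  }
})

test_that("node relabelling permutes nodal metrics and fixes global ones", {
  for (s in 1:20) {
    a <- random_connected_graph(9, 0.35, 900 + s)
    set.seed(s); perm <- sample(9)
    b <- a[perm, perm]
    expect_equal(unname(degree_centrality(b)),
                 unname(degree_centrality(a))[perm])
    expect_equal(unname(betweenness_centrality(b)),
                 unname(betweenness_centrality(a))[perm], tolerance = 1e-12)
    expect_equal(unname(local_efficiency(b)),
                 unname(local_efficiency(a))[perm])
    expect_equal(global_efficiency(b), global_efficiency(a))
    expect_equal(characteristic_path_length(b),
                 characteristic_path_length(a))
    expect_equal(clustering_coefficient(b)$mean,
                 clustering_coefficient(a)$mean)
  }
})

test_that("modularity optimizer finds planted two-clique structure", {
  # two 5-cliques joined by one bridge; Q of {clique1, clique2} = 0.4543...
  g <- complete_graph(10)
  g[1:5, 6:10] <- 0L; g[6:10, 1:5] <- 0L
  g[5, 6] <- g[6, 5] <- 1L
  res <- modularity(g, seed = 3)
  # exhaustive check over all partitions is infeasible at 10 nodes here;
  # planted-partition Q computed by hand from the definition:
  m2 <- sum(g)           # 2m = 42
  q_planted <- (20 / m2 - (21 / m2)^2) * 2
  expect_gte(res$Q + 1e-9, q_planted)
  expect_gt(res$Q, 0.3)
  expect_lt(res$Q, 0.5)
  # the found partition separates the cliques
  expect_equal(length(unique(res$membership[1:5])), 1)
  expect_equal(length(unique(res$membership[6:10])), 1)
  expect_false(res$membership[1] == res$membership[10])
  # optimizer sanity: beats all-singletons (Q_singletons < 0)
  expect_gt(res$Q, 0)
  expect_warning(q0 <- modularity(matrix(0L, 4, 4), seed = 1)$Q, "edgeless")
  expect_true(is.na(q0))
})

test_that("modularity on small graphs equals exhaustive partition search", {
  # all set partitions of 6-7 node graphs via restricted growth strings
  all_partitions <- function(n) {
    out <- list()
    rec <- function(prefix, maxc) {
      k <- length(prefix)
      if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
      for (c in seq_len(maxc + 1)) rec(c(prefix, c), max(maxc, c))
    }
    rec(1L, 1L)
    out
  }
  q_of <- function(a, memb) {
    m2 <- sum(a)
    if (m2 == 0) return(NA_real_)
    q <- 0
    for (c in unique(memb)) {
      idx <- memb == c
      q <- q + sum(a[idx, idx]) / m2 - (sum(a[idx, ]) / m2)^2
    }
    q
  }
  for (s in 1:5) {
    n <- 6
    a <- random_connected_graph(n, 0.45, 4200 + s)
    qs <- vapply(all_partitions(n), function(p) q_of(a, p), numeric(1))
    expect_equal(modularity(a, seed = s, restarts = 10)$Q, max(qs),
                 tolerance = 1e-10)
  }
})

test_that("degree-preserving rewiring conserves degrees and edges", {
  for (s in 1:10) {
    a <- random_connected_graph(20, 0.25, 300 + s)
    r <- randomized_reference(a, seed = s)
    expect_equal(rowSums(r), rowSums(a))
    expect_equal(sum(r), sum(a))
    expect_equal(unname(diag(r)), rep(0, 20))
  }
  expect_warning(randomized_reference(sym_adj(3, c(1, 2)), seed = 1),
                 "impossible")
})

test_that("rewiring leaves Erdos-Renyi clustering unchanged on average", {
  # ER graphs are already degree-random: rewired clustering should match
  # input clustering within 3 SE over replicates
  a <- random_graph(60, 0.15, 12)
  cc_in <- clustering_coefficient(a)$mean
  cc_refs <- vapply(1:40, function(r)
    clustering_coefficient(randomized_reference(a, seed = r))$mean,
    numeric(1))
  se <- sd(cc_refs) / sqrt(length(cc_refs))
  expect_lt(abs(mean(cc_refs) - cc_in), 3 * se + 0.01)
})

test_that("AUC quadrature is exact for constant and linear curves", {
  grid <- density_grid_default()
  expect_length(grid, 28)
  expect_equal(auc(rep(3, 28), grid), 0.27 * 3, tolerance = 1e-12)
  expect_equal(auc(grid, grid), (0.37^2 - 0.10^2) / 2, tolerance = 1e-12)
  expect_equal(auc(grid, grid), 0.063450, tolerance = 1e-9)
  expect_error(auc(1:3, grid), "length")
  expect_true(is.na(auc(c(1, NA, 1), c(0.1, 0.2, 0.3))))
})

test_that("metric curves are deterministic and monotone where expected", {
  tab <- tiny_cohort(n_hc = 6, n_patient = 2, seed = 21)
  m <- fit_normative_model(tab[tab$group == "HC", ])
  z <- compute_deviation(tab, m)
  w <- build_similarity_network(z[1, ])
  st <- build_graph_stack(w, density_grid_default(0.09))
  mc1 <- metric_curves(st, "s", m_refs = 5, seed = 9)
  mc2 <- metric_curves(st, "s", m_refs = 5, seed = 9)
  expect_identical(mc1, mc2)
  expect_false(identical(
    mc1$global$sigma,
    metric_curves(st, "s", m_refs = 5, seed = 10)$global$sigma))
  # nested stacks: degree and global efficiency never decrease with density
  expect_true(all(apply(mc1$nodal$degree, 1, function(v) all(diff(v) >= 0))))
  expect_true(all(diff(mc1$global$global_efficiency) >= 0))
  expect_equal(length(mc1$global$Cp), length(st$densities))
  expect_true(all(is.finite(mc1$global_auc[c("global_efficiency", "Cp")])))
})

test_that("engine agrees with igraph on study-sized graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    a <- random_graph(82, 0.2, 8800 + s)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(unname(degree_centrality(a)), igraph::degree(g))
    D <- igraph::distances(g)
    expect_equal(unname(shortest_paths(a)), unname(D))
    bc <- igraph::betweenness(g, normalized = TRUE)
    expect_equal(unname(betweenness_centrality(a)), unname(bc),
                 tolerance = 1e-10)
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(unname(clustering_coefficient(a)$node), unname(cc),
                 tolerance = 1e-12)
    inv <- 1 / D; diag(inv) <- 0
    expect_equal(global_efficiency(a), mean(inv[row(inv) != col(inv)]),
                 tolerance = 1e-12)
    # Q of our partition evaluated by igraph matches our Q
    res <- modularity(a, seed = s)
    expect_equal(igraph::modularity(g, res$membership), res$Q,
                 tolerance = 1e-12)
  }
})
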