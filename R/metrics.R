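# Binary-graph metric engine (R surface over the compiled core).
# Conventions for disconnected graphs: efficiency-style metrics use
# 1/infinity = 0; characteristic path length averages over reachable pairs.

#' Degree centrality
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return integer vector of per-node edge counts.
#' @export
degree_centrality <- function(adj) {
  adj <- check_adjacency(adj, "degree_centrality")
  rowSums(adj)
}

#' Pairwise shortest-path (hop) distances
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return numeric matrix of BFS distances; unreachable pairs are `Inf`,
#'   diagonal 0.
#' @export
shortest_paths <- function(adj) {
  adj <- check_adjacency(adj, "shortest_paths")
  D <- .cpp_bfs_distances(adj)
  dimnames(D) <- dimnames(adj)
  D
}

#' Characteristic path length
#'
#' Mean hop distance over reachable ordered pairs (self-pairs excluded).
#' On disconnected graphs unreachable pairs are dropped from the average
#' (reachable-pairs convention); `NaN` with a warning if no pair is
#' reachable.
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return scalar.
#' @export
characteristic_path_length <- function(adj) {
  D <- shortest_paths(adj)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (!length(d)) {
    warning("no reachable pairs; characteristic path length undefined")
    return(NaN)
  }
  mean(d)
}

#' Global efficiency
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return mean of 1/distance over ordered pairs (unreachable contributes 0).
#' @export
global_efficiency <- function(adj) {
  D <- shortest_paths(adj)
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return per-node mean of 1/distance to all other nodes.
#' @export
nodal_efficiency <- function(adj) {
  D <- shortest_paths(adj)
  n <- nrow(D)
  if (n < 2) return(rep(0, n))
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Clustering coefficient
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return list with per-node coefficients (`node`; 0 for degree < 2) and
#'   their mean (`mean`, the network Cp).
#' @export
clustering_coefficient <- function(adj) {
  adj <- check_adjacency(adj, "clustering_coefficient")
  cc <- .cpp_clustering(adj)
  names(cc) <- rownames(adj)
  list(node = cc, mean = mean(cc))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbours
#' (the node itself excluded); 0 for nodes with fewer than 2 neighbours.
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return per-node numeric vector.
#' @export
local_efficiency <- function(adj) {
  adj <- check_adjacency(adj, "local_efficiency")
  le <- .cpp_local_efficiency(adj)
  names(le) <- rownames(adj)
  le
}

#' Betweenness centrality
#'
#' Brandes accumulation of shortest-path pair dependencies, normalized by
#' `(N-1)(N-2)/2` so values lie in [0, 1].
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @return per-node numeric vector.
#' @export
betweenness_centrality <- function(adj) {
  adj <- check_adjacency(adj, "betweenness_centrality")
  n <- nrow(adj)
  bc <- .cpp_betweenness(adj)
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(adj)
  bc
}

#' Newman modularity of the best partition found
#'
#' Seeded Louvain optimization (local moving + aggregation) with random
#' restarts; the best-Q partition is returned. Greedy community optimizers
#' are order-sensitive, hence the explicit seed and restarts.
#' @param adj binary symmetric zero-diagonal adjacency matrix with >= 1 edge.
#' @param seed integer seed.
#' @param restarts number of restarts (best Q kept).
#' @return list with `Q` and `membership` (1-based community labels);
#'   `Q = NA` with a warning on edgeless graphs.
#' @export
modularity <- function(adj, seed = 1L, restarts = 10L) {
  adj <- check_adjacency(adj, "modularity")
  if (sum(adj) == 0) {
    warning("edgeless graph: modularity undefined")
    return(list(Q = NA_real_, membership = rep(NA_integer_, nrow(adj))))
  }
  res <- .cpp_louvain(adj, as.integer(restarts), as.numeric(seed))
  list(Q = res$Q, membership = res$membership + 1L)
}

#' Degree-preserving randomized reference graph
#'
#' Maslov-Sneppen double-edge-swap rewiring: preserves every node's degree
#' and the edge count; connectedness is not enforced. If fewer than 2 edges
#' exist (or the graph admits no swap, e.g. a star) the input is returned
#' with a warning after the attempted swaps.
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @param n_swaps number of attempted swaps (default 10 x edge count).
#' @param seed integer seed.
#' @return rewired adjacency matrix.
#' @export
randomized_reference <- function(adj, n_swaps = NULL, seed = 1L) {
  adj <- check_adjacency(adj, "randomized_reference")
  edges <- adj_to_edges(adj)
  m <- nrow(edges)
  if (m < 2) {
    warning("fewer than 2 edges: rewiring impossible, returning input")
    return(adj)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  out <- .cpp_double_edge_swap(edges - 1L, nrow(adj), as.integer(n_swaps),
                               as.numeric(seed))
  res <- edges_to_adj(out + 1L, nrow(adj))
  dimnames(res) <- dimnames(adj)
  if (identical(unname(res), unname(adj)) && n_swaps > 0)
    warning("no swap was accepted (e.g. star graph): rewiring impossible, ",
            "returning input")
  res
}

#' Small-world indices against degree-preserving random references
#'
#' `gamma = Cp / mean(Cp_rand)`, `lambda = Lp / mean(Lp_rand)`,
#' `sigma = gamma / lambda`, with `m_refs` rewired references generated by
#' [randomized_reference()] under per-reference derived seeds.
#' @param adj binary symmetric zero-diagonal adjacency matrix.
#' @param m_refs number of random references (>= 1).
#' @param n_swaps swaps per reference (default 10 x edge count).
#' @param seed integer seed.
#' @return named numeric vector `c(gamma, lambda, sigma)`; `NA` with a
#'   warning when the reference clustering or path length averages to 0.
#' @export
small_world_indices <- function(adj, m_refs = 100L, n_swaps = NULL,
                                seed = 1L) {
  adj <- check_adjacency(adj, "small_world_indices")
  stopifnot(m_refs >= 1)
  cp <- clustering_coefficient(adj)$mean
  lp <- characteristic_path_length(adj)
  edges <- adj_to_edges(adj)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(edges)
  ref_seeds <- vapply(seq_len(m_refs), function(r) derive_seed(seed, "ref", r),
                      numeric(1))
  refstats <- .cpp_sw_refs(edges - 1L, nrow(adj), as.integer(n_swaps),
                           ref_seeds)
  cps <- refstats[, 1]
  lps <- refstats[, 2]
  mc <- mean(cps)
  ml <- mean(lps[is.finite(lps)])
  if (!is.finite(mc) || mc == 0 || !is.finite(ml) || ml == 0) {
    warning("reference clustering/path length degenerate; indices undefined")
    return(c(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_))
  }
  g <- cp / mc
  l <- lp / ml
  c(gamma = g, lambda = l, sigma = g / l)
}

#' Trapezoidal area under a metric-versus-density curve
#' @param curve metric values along the grid.
#' @param grid density grid (same length as `curve`, >= 2 points).
#' @return scalar AUC; `NA` if any curve value is missing (undefined points
#'   are never silently interpolated).
#' @export
auc <- function(curve, grid) {
  if (length(curve) != length(grid))
    stop("curve and grid lengths differ", call. = FALSE)
  if (length(grid) < 2)
    stop("need at least 2 grid points", call. = FALSE)
  if (any(!is.finite(curve))) return(NA_real_)
  sum((curve[-1] + curve[-length(curve)]) / 2 * diff(grid))
}

#' Metric curves and AUCs for one subject's graph stack
#'
#' Evaluates every nodal metric (degree centrality, nodal efficiency, local
#' efficiency, clustering, betweenness) and every global metric (global
#' efficiency, characteristic path length, mean clustering Cp, gamma,
#' lambda, sigma, modularity Q) at each density of the stack, and the
#' trapezoidal AUC of each curve over the grid. Stochastic metrics (the
#' small-world references, the modularity optimizer) draw their seeds from
#' `(seed, subject_id, density)` so curves are reproducible subject by
#' subject.
#'
#' @param stack a `graph_stack`.
#' @param subject_id label used in seed derivation and output.
#' @param m_refs random references per density for gamma/lambda/sigma.
#' @param n_swaps swaps per reference (default 10 x edge count).
#' @param restarts modularity restarts.
#' @param seed master seed.
#' @param small_world if `FALSE`, skip the (expensive) reference-based
#'   indices and modularity; their curves are `NA`.
#' @return object of class `metric_curves`: list with `subject_id`,
#'   `densities`, `nodal` (list of metric -> nodes x densities matrix),
#'   `global` (metric -> vector), `nodal_auc` (metric -> per-node vector),
#'   `global_auc` (named vector).
#' @export
metric_curves <- function(stack, subject_id = "subject", m_refs = 100L,
                          n_swaps = NULL, restarts = 10L, seed = 1L,
                          small_world = TRUE) {
  stopifnot(inherits(stack, "graph_stack"))
  grid <- stack$densities
  nd <- length(grid)
  n <- nrow(stack$adjacency[[1]])
  nodal_names <- c("degree", "nodal_efficiency", "local_efficiency",
                   "clustering", "betweenness")
  global_names <- c("global_efficiency", "char_path_length", "Cp",
                    "gamma", "lambda", "sigma", "Q")
  nodal <- lapply(nodal_names, function(x) matrix(NA_real_, n, nd))
  names(nodal) <- nodal_names
  globalm <- lapply(global_names, function(x) rep(NA_real_, nd))
  names(globalm) <- global_names

  for (k in seq_len(nd)) {
    adj <- stack$adjacency[[k]]
    nodal$degree[, k] <- degree_centrality(adj)
    nodal$nodal_efficiency[, k] <- nodal_efficiency(adj)
    nodal$local_efficiency[, k] <- local_efficiency(adj)
    cc <- clustering_coefficient(adj)
    nodal$clustering[, k] <- cc$node
    nodal$betweenness[, k] <- betweenness_centrality(adj)
    globalm$global_efficiency[k] <- global_efficiency(adj)
    globalm$char_path_length[k] <- suppressWarnings(
      characteristic_path_length(adj))
    globalm$Cp[k] <- cc$mean
    if (small_world) {
      sw <- small_world_indices(
        adj, m_refs = m_refs, n_swaps = n_swaps,
        seed = derive_seed(seed, "sw", subject_id, grid[k]))
      globalm$gamma[k] <- sw[["gamma"]]
      globalm$lambda[k] <- sw[["lambda"]]
      globalm$sigma[k] <- sw[["sigma"]]
      globalm$Q[k] <- modularity(
        adj, seed = derive_seed(seed, "mod", subject_id, grid[k]),
        restarts = restarts)$Q
    }
  }
  rn <- rownames(stack$adjacency[[1]])
  for (m in nodal_names) rownames(nodal[[m]]) <- rn
  nodal_auc <- lapply(nodal, function(mat)
    apply(mat, 1, function(v) auc(v, grid)))
  global_auc <- vapply(globalm, function(v) auc(v, grid), numeric(1))
  structure(list(subject_id = subject_id, densities = grid, nodal = nodal,
                 global = globalm, nodal_auc = nodal_auc,
                 global_auc = global_auc),
            class = "metric_curves")
}
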