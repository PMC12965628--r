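# Individual deviation-similarity networks and density thresholding.
# Edge weight between regions i and j of one subject:
#   w_ij = exp(-(z_i - z_j)^2)  in (0, 1],  w = 1 iff z_i = z_j,
# i.e. regions deviating from the HC norm in the same way are strongly
# connected. Binarization keeps the top-k weights at a target density.

#' Build one subject's deviation-similarity network
#'
#' @param z length-82 (or length-N) numeric vector of deviation z-scores.
#' @return an N x N symmetric matrix with `w[i,j] = exp(-(z[i]-z[j])^2)` off
#'   the diagonal and 0 on the diagonal (no self-loops).
#' @export
build_similarity_network <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("z-scores must be finite numeric", call. = FALSE)
  d <- outer(z, z, "-")
  w <- exp(-d^2)
  diag(w) <- 0
  dimnames(w) <- list(names(z), names(z))
  w
}

# deterministic ranking of upper-triangle weights: by descending weight,
# ties broken by ascending (i, j) row-major pair order
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Binarize a weighted network at a target density
#'
#' Keeps the `k = floor(d * N(N-1)/2)` strongest off-diagonal weights as
#' edges; ties are broken deterministically by ascending (i, j) pair index.
#'
#' @param w symmetric weight matrix (diagonal ignored).
#' @param d density in (0, 1].
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
binarize_at_density <- function(w, d) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0 || d > 1)
    stop("density must be a single value in (0, 1]", call. = FALSE)
  n <- nrow(w)
  pairs <- upper_pairs(n)
  wt <- w[pairs]
  k <- floor(d * n * (n - 1) / 2)
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  if (k > 0) {
    ord <- order(-wt, seq_along(wt))   # stable: ties by pair order
    keep <- pairs[ord[seq_len(min(k, length(wt)))], , drop = FALSE]
    adj[keep] <- 1L
    adj[keep[, c(2, 1), drop = FALSE]] <- 1L
  }
  adj
}

#' Build a nested stack of binary graphs over a density grid
#'
#' @param w symmetric weight matrix.
#' @param grid ascending density grid, e.g. `density_grid_default()`.
#' @return object of class `graph_stack`: list with `densities` and
#'   `adjacency` (one binary matrix per density). Because each adjacency is
#'   the top-k of the same weight ranking, stacks are nested: every edge at
#'   density d is present at any d' > d.
#' @export
build_graph_stack <- function(w, grid = density_grid_default()) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("density grid must be strictly ascending", call. = FALSE)
  adj <- lapply(grid, function(d) binarize_at_density(w, d))
  structure(list(densities = grid, adjacency = adj), class = "graph_stack")
}

#' The fixed density grid: 0.10 to 0.37 in steps of 0.01 (28 levels)
#' @param step grid step (default 0.01; a coarser step thins the grid for
#'   faster exploratory runs).
#' @return numeric vector of densities.
#' @export
density_grid_default <- function(step = 0.01) {
  round(seq(0.10, 0.37, by = step), 10)
}

#' Determine a usable density range from retention criteria
#'
#' In `mode = "fixed"` (the default) returns the standard grid 0.10-0.37,
#' step 0.01. In `mode = "criteria"` evaluates, at each candidate density
#' and for every subject's binarized graph: (1) more than 80% of nodes
#' non-isolated; (2) modularity of the best partition > 0.3;
#' (3) small-worldness sigma > 1 - and returns the longest contiguous run of
#' candidate densities at which all subjects pass all three.
#'
#' @param networks list of weight matrices (one per subject).
#' @param candidate ascending candidate densities.
#' @param mode `"fixed"` or `"criteria"`.
#' @param min_connected_frac,min_modularity,min_sigma criterion thresholds.
#' @param m_refs,n_swaps_factor,restarts settings passed to the metric
#'   engine for criteria evaluation.
#' @param seed criterion seed (fixed so range selection is reproducible).
#' @return the selected density grid (numeric vector).
#' @export
determine_density_range <- function(networks, candidate = density_grid_default(),
                                    mode = c("fixed", "criteria"),
                                    min_connected_frac = 0.8,
                                    min_modularity = 0.3, min_sigma = 1,
                                    m_refs = 20, n_swaps_factor = 10,
                                    restarts = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    message("density range selection disabled; using fixed grid 0.10-0.37")
    return(density_grid_default())
  }
  if (!length(networks)) stop("need at least one network", call. = FALSE)
  if (is.unsorted(candidate, strictly = TRUE))
    stop("candidate grid must be strictly ascending", call. = FALSE)

  pass <- matrix(NA, length(candidate), 3,
                 dimnames = list(NULL, c("connected", "modularity",
                                         "small_world")))
  for (di in seq_along(candidate)) {
    d <- candidate[di]
    ok <- c(TRUE, TRUE, TRUE)
    for (si in seq_along(networks)) {
      adj <- binarize_at_density(networks[[si]], d)
      deg <- rowSums(adj)
      ok[1] <- ok[1] && mean(deg > 0) > min_connected_frac
      if (ok[2]) {
        q <- modularity(adj, seed = derive_seed(seed, "crit-mod", si, d),
                        restarts = restarts)$Q
        ok[2] <- !is.na(q) && q > min_modularity
      }
      if (ok[3]) {
        sw <- small_world_indices(adj, m_refs = m_refs,
                                  n_swaps = n_swaps_factor * sum(adj) / 2,
                                  seed = derive_seed(seed, "crit-sw", si, d))
        ok[3] <- is.finite(sw[["sigma"]]) && sw[["sigma"]] > min_sigma
      }
      if (!any(ok)) break
    }
    pass[di, ] <- ok
  }
  all_ok <- rowSums(pass) == 3
  if (!any(all_ok)) {
    diag_txt <- paste(sprintf("%s: %d/%d densities pass", colnames(pass),
                              colSums(pass), length(candidate)),
                      collapse = "; ")
    stop("no candidate density satisfies all retention criteria (", diag_txt,
         ")", call. = FALSE)
  }
  # longest contiguous run of passing densities
  r <- rle(all_ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- which(r$values)[which.max(r$lengths[r$values])]
  candidate[starts[best]:ends[best]]
}

#' Build all subjects' networks from deviation z-scores
#'
#' @param z matrix of z-scores (subjects x regions), from
#'   [compute_deviation()].
#' @return named list of similarity weight matrices.
#' @export
build_all_networks <- function(z) {
  nets <- lapply(seq_len(nrow(z)), function(i) build_similarity_network(z[i, ]))
  names(nets) <- rownames(z)
  nets
}
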