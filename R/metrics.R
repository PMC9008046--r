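#' Construct a weighted undirected graph
#'
#' A thin validated container: symmetric non-negative weight matrix
#' with zero diagonal and finite entries. Coherence graphs convert
#' directly via [as_weighted_graph()].
#'
#' @param W Symmetric numeric matrix, non-negative, zero diagonal.
#' @param node_labels Optional node names (defaults to rownames or
#'   `v1..vn`).
#' @return A `weighted_graph`.
#' @export
weighted_graph <- function(W, node_labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (!all(is.finite(W))) stop("W must be finite")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  W <- (W + t(W)) / 2
  if (any(W < 0)) stop("W must be non-negative")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  labels <- node_labels %||% rownames(W) %||%
    paste0("v", seq_len(nrow(W)))
  structure(list(W = W, node_labels = labels), class = "weighted_graph")
}

#' @rdname weighted_graph
#' @param g A `coherence_graph` (or anything with `$W` and labels).
#' @param edge_threshold Weights at or below this value are set to 0
#'   (default 0 keeps the graph dense).
#' @export
as_weighted_graph <- function(g, edge_threshold = 0) {
  W <- g$W
  W[W <= edge_threshold] <- 0
  weighted_graph(W, g$channel_labels %||% g$node_labels)
}

#' Average degree and strength
#'
#' Node degree counts incident edges with weight above `threshold`
#' (default 0); node strength sums incident weights. Both are averaged
#' over nodes. On a dense coherence graph the average degree is simply
#' N - 1.
#'
#' @param g A `weighted_graph`.
#' @param threshold Edge-presence threshold for the degree count.
#' @return List with `degree` and `strength`.
#' @export
degree_strength <- function(g, threshold = 0) {
  A <- g$W > threshold
  list(degree = mean(rowSums(A)), strength = mean(rowSums(g$W)))
}

#' All-pairs shortest-path distances
#'
#' Connection lengths are the inverse weights, L_ij = 1/W_ij for
#' W_ij > 0 (infinite otherwise) — the standard transform for
#' connectivity weights, where strong coupling means short functional
#' distance. Distances are computed by Dijkstra's algorithm;
#' disconnected pairs come back as `Inf` and the diagonal is 0.
#'
#' @param g A `weighted_graph`.
#' @return Numeric matrix of shortest-path lengths.
#' @export
distance_matrix <- function(g) {
  len <- ifelse(g$W > 0, 1 / g$W, Inf)
  diag(len) <- Inf
  cpp_dijkstra_all(len)
}

#' Global path-based measures
#'
#' From a shortest-path distance matrix: eccentricity of a node is its
#' maximal finite distance to any other node; radius and diameter are
#' the minimum and maximum eccentricity; characteristic path length is
#' the mean finite off-diagonal distance; global efficiency is the mean
#' inverse distance (1/Inf = 0 for disconnected pairs).
#'
#' @param d Distance matrix from [distance_matrix()].
#' @return List with `radius`, `diameter`, `characteristic_path_length`,
#'   `global_efficiency`.
#' @export
path_measures <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  off <- d
  diag(off) <- NA
  ecc <- apply(off, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) NA_real_ else max(r)
  })
  fin <- off[is.finite(off)]
  inv <- 1 / off
  inv[!is.finite(off)] <- 0
  diag(inv) <- NA
  list(radius = min(ecc, na.rm = TRUE),
       diameter = max(ecc, na.rm = TRUE),
       characteristic_path_length = mean(fin),
       global_efficiency = mean(inv, na.rm = TRUE))
}

# Onnela geometric-mean triangle intensities; weights rescaled by the
# maximum so clustering of a coherence graph does not depend on overall
# coupling scale. Returns the per-node cycle intensity and binary degree.
onnela_cycles <- function(W) {
  mx <- max(W)
  Wh <- if (mx > 0) (W / mx)^(1 / 3) else W
  list(cyc = diag(Wh %*% Wh %*% Wh), k = rowSums(W > 0))
}

#' Weighted clustering coefficient and transitivity
#'
#' Per-node clustering uses the geometric-mean (Onnela) triangle
#' intensity: the sum over neighbour pairs of
#' `(w_ij w_ih w_jh)^(1/3)` (weights rescaled by max W), normalised by
#' `k_i (k_i - 1)`. Nodes with fewer than two neighbours contribute 0.
#' Transitivity is the ratio of total triangle intensity to total
#' connected triples under the same weight convention.
#'
#' @param g A `weighted_graph`.
#' @return List with `clustering_coefficient` (mean over nodes) and
#'   `transitivity`.
#' @export
clustering_transitivity <- function(g) {
  oc <- onnela_cycles(g$W)
  denom <- oc$k * (oc$k - 1)
  Ci <- ifelse(denom > 0, oc$cyc / denom, 0)
  Tr <- if (sum(denom) > 0) sum(oc$cyc) / sum(denom) else 0
  list(clustering_coefficient = mean(Ci), transitivity = Tr)
}

#' Mean weighted local efficiency
#'
#' For each node, the efficiency of communication among its neighbours
#' when the node is removed, in the cube-root weighted convention:
#' inverse shortest-path distances between neighbours j,h are computed
#' on the cube-rooted connection lengths of the neighbour subgraph, and
#' each pair contributes `(w_ij w_ih)^(1/3)` times that inverse
#' distance, normalised by `k_i (k_i - 1)`. Nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param g A `weighted_graph`.
#' @return Mean local efficiency over nodes.
#' @export
local_efficiency <- function(g) {
  W <- g$W
  n <- nrow(W)
  eloc <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(W[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sw <- W[u, nb]^(1 / 3)
    sub <- W[nb, nb, drop = FALSE]
    len <- ifelse(sub > 0, (1 / sub)^(1 / 3), Inf)
    diag(len) <- Inf
    e <- 1 / cpp_dijkstra_all(len)
    e[!is.finite(e)] <- 0
    diag(e) <- 0
    eloc[u] <- sum(outer(sw, sw) * e) / (k * (k - 1))
  }
  mean(eloc)
}

# Newman modularity of a partition on weighted adjacency W
modularity_q <- function(W, membership, gamma = 1) {
  m2 <- sum(W)
  if (m2 <= 0) stop("zero-weight graph")
  k <- rowSums(W)
  S <- outer(membership, membership, "==")
  sum((W - gamma * outer(k, k) / m2) * S) / m2
}

#' Louvain community detection with restarts
#'
#' Maximises weighted Newman modularity
#' `Q = (1/2m) * sum_ij (W_ij - gamma k_i k_j / 2m) delta(c_i, c_j)`
#' by the Louvain heuristic, run `restarts` times with independently
#' randomised node visiting orders; the partition with the best Q wins.
#' Randomness comes from R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param g A `weighted_graph` with positive total weight.
#' @param gamma Resolution parameter (default 1).
#' @param restarts Number of randomised restarts (default 10).
#' @return List with `Q` and integer `partition` (1-based module
#'   labels).
#' @export
louvain_modularity <- function(g, gamma = 1, restarts = 10) {
  W <- g$W
  if (sum(W) <= 0) stop("zero-weight graph")
  n <- nrow(W)
  best_q <- -Inf
  best_m <- rep(1L, n)
  for (r in seq_len(restarts)) {
    ord <- sample.int(n)
    m <- cpp_louvain(W, gamma, ord)
    q <- modularity_q(W, m, gamma)
    if (q > best_q + 1e-14) { best_q <- q; best_m <- m }
  }
  # the one-module partition is always admissible (Q = 0 at gamma = 1)
  q1 <- modularity_q(W, rep(1L, n), gamma)
  if (q1 > best_q) { best_q <- q1; best_m <- rep(1L, n) }
  list(Q = best_q, partition = best_m)
}

#' Weighted assortativity
#'
#' Weight-respecting variant of degree assortativity: the Pearson
#' correlation of endpoint strengths over edges, with each edge
#' contributing proportionally to its weight. If endpoint strengths are
#' all equal (e.g. a regular ring) the correlation is undefined and is
#' reported as 0 with a warning.
#'
#' @param g A `weighted_graph` with at least 2 edges.
#' @return Scalar assortativity in \[-1, 1\].
#' @export
assortativity_weighted <- function(g) {
  W <- g$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("need at least 2 edges")
  s <- rowSums(W)
  w <- W[idx]
  x <- s[idx[, 1]]; y <- s[idx[, 2]]
  sw <- sum(w)
  # symmetrised weighted moments (each edge seen from both ends)
  m1 <- sum(w * (x + y) / 2) / sw
  m2 <- sum(w * (x^2 + y^2) / 2) / sw
  mxy <- sum(w * x * y) / sw
  v <- m2 - m1^2
  if (v <= 1e-15 * max(m2, 1)) {
    warning("degenerate endpoint-strength variance; assortativity set to 0")
    return(0)
  }
  (mxy - m1^2) / v
}

#' Small-worldness sigma
#'
#' `sigma = (C / <C_null>) / (L / <L_null>)` where C is the mean
#' weighted (Onnela) clustering coefficient, L the weighted
#' characteristic path length, and the null networks are Maslov-Sneppen
#' degree-preserving rewirings that retain the weight multiset (weights
#' travel with edges). Averages are over `n_null` independent nulls.
#' On a complete graph no rewiring is possible and sigma is exactly 1.
#'
#' @param g A `weighted_graph`, connected enough for a finite L.
#' @param n_null Number of null networks (default 20).
#' @param rewires_per_edge Swap attempts per edge per null (default 10).
#' @return Scalar sigma.
#' @export
small_worldness <- function(g, n_null = 20, rewires_per_edge = 10) {
  if (n_null < 1) stop("n_null must be >= 1")
  # numerator C and L through the same code path as the nulls (zero
  # rewires = the original graph), so that when no rewiring is possible
  # (complete graph) sigma is exactly 1
  base <- cpp_smallworld_nulls(g$W, 1L, 0L)
  nulls <- cpp_smallworld_nulls(g$W, as.integer(n_null),
                                as.integer(rewires_per_edge))
  # triangle-free graph and triangle-free nulls: equal clustering, so
  # the ratio is taken as 1 rather than 0/0
  c_ratio <- if (base[1, 1] == 0 && mean(nulls[, 1]) == 0) 1 else
    base[1, 1] / mean(nulls[, 1])
  c_ratio / (base[1, 2] / mean(nulls[, 2]))
}

#' All twelve global graph measures
#'
#' One call computing the full record for a subject x band graph:
#' average degree, average strength, radius, diameter, characteristic
#' path length, global efficiency, local efficiency, clustering
#' coefficient, transitivity, Louvain modularity, weighted
#' assortativity and small-worldness. The stochastic measures
#' (modularity restarts, small-world nulls) draw from R's RNG; pass
#' `seed` for a reproducible record.
#'
#' @param g A `weighted_graph`.
#' @param config Pipeline configuration (for the Louvain, small-world
#'   and degree-threshold settings); default [default_config()].
#' @param seed Optional integer seed.
#' @return Named list of the twelve measures.
#' @examples
#' W <- matrix(1, 4, 4); diag(W) <- 0
#' unlist(all_metrics(weighted_graph(W), seed = 1))
#' @export
all_metrics <- function(g, config = default_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- degree_strength(g, threshold = config$edge_threshold %||% 0)
  d <- distance_matrix(g)
  pm <- path_measures(d)
  ct <- clustering_transitivity(g)
  lv <- louvain_modularity(g,
                           gamma = config$louvain$gamma %||% 1,
                           restarts = config$louvain$restarts %||% 10)
  sw <- small_worldness(g,
                        n_null = config$smallworld$n_null %||% 20,
                        rewires_per_edge =
                          config$smallworld$rewires_per_edge %||% 10)
  list(degree = ds$degree,
       strength = ds$strength,
       radius = pm$radius,
       diameter = pm$diameter,
       characteristic_path_length = pm$characteristic_path_length,
       global_efficiency = pm$global_efficiency,
       local_efficiency = local_efficiency(g),
       clustering_coefficient = ct$clustering_coefficient,
       transitivity = ct$transitivity,
       modularity = lv$Q,
       assortativity = assortativity_weighted(g),
       small_worldness = sw)
}

#' Graph measures for a whole cohort
#'
#' Runs [subject_connectivity()] and [all_metrics()] for every subject
#' and band, returning the long table consumed by [compare_groups()].
#' Per-subject seeds are derived from `config$seed` by counter, so the
#' result does not depend on evaluation order.
#'
#' @param subjects List of `epoch_set` objects.
#' @param config Pipeline configuration.
#' @return Data.frame with columns `subject_id`, `band`, `measure`,
#'   `value`.
#' @export
cohort_metrics <- function(subjects, config = default_config()) {
  bands <- config$bands
  n_meas <- 12L
  per_subj <- nrow(bands) * n_meas
  vals <- numeric(length(subjects) * per_subj)
  band_col <- meas_col <- id_col <- character(length(vals))
  pos <- 0L
  for (i in seq_along(subjects)) {
    gs <- subject_connectivity(subjects[[i]], bands = bands)
    for (b in seq_along(gs)) {
      g <- as_weighted_graph(gs[[b]],
                             edge_threshold = config$edge_threshold %||% 0)
      m <- all_metrics(g, config,
                       seed = derive_seed(config$seed %||% 1,
                                          i * 131L + b))
      idx <- pos + seq_len(n_meas)
      vals[idx] <- unlist(m, use.names = FALSE)
      meas_col[idx] <- names(m)
      band_col[idx] <- names(gs)[b]
      id_col[idx] <- subjects[[i]]$subject_id
      pos <- pos + n_meas
    }
  }
  data.frame(subject_id = id_col, band = band_col, measure = meas_col,
             value = vals, stringsAsFactors = FALSE)
}
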