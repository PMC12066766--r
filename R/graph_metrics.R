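#' Weighted brain graph from a connectivity result
#'
#' One node per channel; edge weights are a map of the *unthresholded*
#' Pearson correlations (thresholding is deliberately avoided for the
#' graph metrics to prevent threshold biases). The default map is the
#' absolute value, because the weighted metric formulas (geometric means,
#' inverse path lengths) require weights in `[0, 1]`; `"clip"` instead
#' zeroes negative correlations.
#'
#' @param conn an `fc_result` (or a plain symmetric correlation matrix).
#' @param weight_map `"abs"` (default) or `"clip"`.
#' @return a `brain_graph`: list with weight matrix `w` (symmetric, zero
#'   diagonal) and the map used.
#' @export
build_weighted_graph <- function(conn, weight_map = c("abs", "clip")) {
  weight_map <- match.arg(weight_map)
  r <- if (inherits(conn, "fc_result")) conn$r else conn
  if (!is.matrix(r) || nrow(r) != ncol(r)) abort("need a square matrix")
  if (anyNA(r)) abort("correlation matrix has missing entries; graph metrics need the full matrix")
  w <- switch(weight_map, abs = abs(r), clip = pmax(r, 0))
  diag(w) <- 0
  if (any(w < 0 | w > 1)) {
    abort("edge weights must lie in [0, 1] after mapping")
  }
  w <- (w + t(w)) / 2 # enforce exact symmetry
  structure(
    list(w = w, weight_map = weight_map,
         participant_id = if (inherits(conn, "fc_result")) conn$participant_id else NULL),
    class = "brain_graph"
  )
}

as_weight_matrix <- function(g) {
  if (inherits(g, "brain_graph")) g$w else g
}

# all-pairs shortest weighted path lengths with length = 1/w
shortest_lengths <- function(w, length_exponent = 1) {
  n <- nrow(w)
  len <- matrix(Inf, n, n)
  pos <- w > 0
  len[pos] <- (1 / w[pos])^length_exponent
  diag(len) <- 0
  ig <- igraph::graph_from_adjacency_matrix(
    ifelse(is.finite(len) & len > 0, len, 0),
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  d <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  diag(d) <- 0
  d
}

#' Weighted global efficiency
#'
#' Mean inverse shortest weighted path length over all ordered node pairs:
#' `E = (1/n) * sum_i [ sum_{j != i} 1/d_ij / (n - 1) ]`, path lengths on
#' edge lengths `1/w`. Disconnected pairs contribute zero. Equals 1 on a
#' complete unit-weight graph, 0 on an empty one.
#'
#' @param g a `brain_graph` or symmetric weight matrix with entries in
#'   `[0, 1]`.
#' @return a single number in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2L) abort("global efficiency needs at least 2 nodes")
  d <- shortest_lengths(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' For each node, the efficiency of its neighborhood subgraph: with
#' neighbors `V` of node `u` (positive-weight edges), cube-rooted stub
#' weights `s_j = w_uj^(1/3)` and shortest paths among `V` computed on
#' cube-rooted lengths `(1/w)^(1/3)` restricted to the neighborhood,
#' `Eloc_u = sum_{j != h in V} s_j s_h / d_jh(V) / (k_u (k_u - 1))`.
#' Nodes with fewer than two neighbors contribute 0; the graph value is
#' the mean over nodes. Equals 1 on a complete unit-weight graph and 0 on
#' a star (leaves have one neighbor, the hub's neighborhood has no edges).
#'
#' @inheritParams global_efficiency
#' @return a single number in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 2L) abort("local efficiency needs at least 2 nodes")
  vals <- vapply(seq_len(n), function(u) {
    V <- which(w[u, ] > 0)
    k <- length(V)
    if (k < 2L) return(0)
    sw <- w[u, V]^(1 / 3)
    dsub <- shortest_lengths(w[V, V, drop = FALSE], length_exponent = 1 / 3)
    inv <- 1 / dsub
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    as.numeric(t(sw) %*% inv %*% sw) / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity around each node:
#' `t_i = (1/2) * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` and
#' `C = (1/n) * sum_i 2 t_i / (k_i (k_i - 1))` with `k_i` the number of
#' positive-weight neighbors; nodes with `k_i < 2` contribute 0.
#'
#' @inheritParams global_efficiency
#' @return a single number in `[0, 1]` for weights in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (n < 1L) abort("clustering coefficient needs at least 1 node")
  W3 <- w^(1 / 3)
  t_i <- diag(W3 %*% W3 %*% W3) / 2
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  mean(c_i)
}

#' Weighted Newman modularity of a given partition
#'
#' Direct evaluation of
#' `Q = (1/2m) * sum_ij (w_ij - gamma * k_i k_j / (2m)) * [c_i == c_j]`
#' with `k_i` the node strength and `2m` twice the total edge weight
#' (`m = l^W`, the sum of all edge weights).
#'
#' @inheritParams global_efficiency
#' @param membership integer community labels, one per node.
#' @param gamma resolution parameter (default 1).
#' @export
modularity_value <- function(g, membership, gamma = 1) {
  w <- as_weight_matrix(g)
  two_m <- sum(w)
  if (two_m <= 0) abort("modularity needs at least one positive weight")
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - gamma * outer(k, k) / two_m) * same) / two_m
}

#' Louvain community detection with restarts
#'
#' Louvain greedy modularity optimization is order-dependent, so the
#' algorithm is run `restarts` times under randomly permuted node orders
#' and the partition with the best modularity is kept. The returned `Q` is
#' always recomputed from the returned partition with the direct Newman
#' formula ([modularity_value()]), never taken on faith from the
#' optimizer.
#'
#' @inheritParams global_efficiency
#' @param gamma resolution parameter.
#' @param restarts number of random restarts (default 20).
#' @param seed RNG seed; results are seed-reproducible.
#' @return list with `membership` (integer labels in node order) and `q`.
#' @export
louvain_modularity <- function(g, gamma = 1, restarts = 20, seed = 1L) {
  w <- as_weight_matrix(g)
  if (sum(w) <= 0) abort("all edge weights are zero; modularity is undefined")
  n <- nrow(w)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      ig <- igraph::graph_from_adjacency_matrix(
        w[perm, perm], mode = "undirected", weighted = TRUE, diag = FALSE
      )
      cl <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight,
                                    resolution = gamma)
      memb <- integer(n)
      memb[perm] <- igraph::membership(cl)
      q <- modularity_value(w, memb, gamma = gamma)
      if (is.null(best) || q > best$q) best <- list(membership = memb, q = q)
    }
  })
  best
}

#' All weighted graph metrics for one participant
#'
#' Convenience wrapper: builds the unthresholded weighted graph and
#' returns the four metrics in one tibble row.
#'
#' @param conn an `fc_result`.
#' @param weight_map see [build_weighted_graph()].
#' @param gamma,restarts,seed Louvain settings.
#' @return one-row tibble: `participant_id`, `global_efficiency`,
#'   `local_efficiency`, `clustering_coefficient`, `modularity`,
#'   `n_nodes`.
#' @export
graph_metrics <- function(conn, weight_map = "abs", gamma = 1, restarts = 20,
                          seed = 1L) {
  g <- build_weighted_graph(conn, weight_map = weight_map)
  lv <- louvain_modularity(g, gamma = gamma, restarts = restarts, seed = seed)
  tibble(
    participant_id = g$participant_id %||% NA_character_,
    global_efficiency = global_efficiency(g),
    local_efficiency = local_efficiency(g),
    clustering_coefficient = clustering_coefficient(g),
    modularity = lv$q,
    n_nodes = nrow(g$w)
  )
}
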