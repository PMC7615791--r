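#' Weighted graph metrics of a BFN
#'
#' Six standard weighted-network statistics on the absolute-weight,
#' zero-diagonal version of the connectivity matrix: mean Onnela weighted
#' clustering coefficient, mean node strength (row sums), mean betweenness
#' centrality on 1/weight distances, Louvain modularity on the weight
#' matrix, and global / mean local efficiency on 1/weight distances.
#' Absolute weights are used because strengths and efficiencies are
#' undefined for signed edges.
#'
#' @param A symmetric connectivity matrix.
#' @param louvain_seed seed for the Louvain community detection.
#' @return named list: `clustering`, `strength`, `betweenness`,
#'   `modularity`, `local_efficiency`, `global_efficiency`.
#' @export
graph_metrics <- function(A, louvain_seed = 1L) {
  check_symmetric(A, tol = 1e-8, name = "A")
  w <- abs(A)
  diag(w) <- 0
  if (all(w == 0)) {
    warning("all-zero network; all metrics are 0")
    return(list(clustering = 0, strength = 0, betweenness = 0,
                modularity = 0, local_efficiency = 0, global_efficiency = 0))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dist_w <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = dist_w)
  comm <- with_seed(louvain_seed,
                    igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  list(clustering = mean(onnela_clustering(w)),
       strength = mean(rowSums(w)),
       betweenness = mean(btw),
       modularity = igraph::modularity(g, igraph::membership(comm),
                                       weights = igraph::E(g)$weight),
       local_efficiency = mean(igraph::local_efficiency(g, weights = dist_w)),
       global_efficiency = igraph::global_efficiency(g, weights = dist_w))
}

# Onnela per-node weighted clustering: weights normalized by the max,
# C_i = (W^(1/3))^3 _ii / (k_i (k_i - 1)); 0 for degree < 2.
onnela_clustering <- function(w) {
  wh <- (w / max(w))^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  c_i
}

#' Graph-metric profiles for a set of BFNs
#'
#' @param bfns list of connectivity matrices.
#' @inheritParams graph_metrics
#' @return data.frame, one row per network.
#' @export
graph_metric_profiles <- function(bfns, louvain_seed = 1L) {
  do.call(rbind, lapply(bfns, function(a)
    as.data.frame(graph_metrics(a, louvain_seed = louvain_seed))))
}
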