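# Whole-network topology metrics compared across seasons and +-BP:
# size, average degree, density, Louvain modularity, average clustering
# and giant-component fraction, all on the unsigned, unweighted skeleton.

#' Topology report for a signed network
#'
#' @param net a [SignedNetwork-class] with at least 2 nodes.
#' @param seed seed for the Louvain community search (the partition, and
#'   hence modularity, is reproducible given the seed).
#' @return one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `average_degree` (2E/N), `density` (2E/(N(N-1))), `modularity`
#'   (Newman Q of the Louvain partition), `n_modules`,
#'   `average_clustering` (mean local clustering, nodes of degree < 2
#'   contributing 0) and `giant_component_fraction`.
#' @export
topology <- function(net, seed = 1L) {
  stopifnot(is(net, "SignedNetwork"))
  n <- nNodes(net)
  if (n < 2L) stop("need at least 2 nodes")
  g <- asIgraph(net)
  # all metrics are defined on the unsigned, unweighted skeleton
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  e <- nEdges(net)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  comp <- igraph::components(g)
  louv <- withSeed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(louv)
  q <- if (e > 0) igraph::modularity(g, memb) else 0
  out <- data.frame(n_nodes = n, n_edges = e,
                    average_degree = 2 * e / n,
                    density = 2 * e / (n * (n - 1)),
                    modularity = q,
                    n_modules = length(unique(memb)),
                    average_clustering = mean(cl),
                    giant_component_fraction = max(comp$csize) / n,
                    stringsAsFactors = FALSE)
  # the partition behind `modularity`, for inspection and verification
  attr(out, "membership") <- stats::setNames(as.integer(memb),
                                             net@nodes$id)
  out
}
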