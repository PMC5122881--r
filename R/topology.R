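#' Connected components, largest first
#'
#' @param graph an undirected `igraph`.
#' @return list of character vectors of node names, sorted by decreasing
#'   size (ties by smallest member name); singletons included.
#' @export
graph_components <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list())
  comp <- igraph::components(graph)
  sets <- split(igraph::V(graph)$name, comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-vapply(sets, length, 0L), vapply(sets, `[`, "", 1L))
  unname(sets[ord])
}

.largest_component <- function(graph) {
  comps <- graph_components(graph)
  if (!length(comps)) stop("graph has no nodes")
  igraph::induced_subgraph(graph, comps[[1]])
}

# Local clustering with the degree < 2 convention -> 0.
.local_clustering <- function(graph) {
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[igraph::degree(graph) < 2] <- 0
  setNames(cc, igraph::V(graph)$name)
}

# Betweenness normalized within each node's own connected component by
# (n_c - 1)(n_c - 2)/2.
.component_betweenness <- function(graph) {
  out <- setNames(numeric(igraph::vcount(graph)), igraph::V(graph)$name)
  for (nodes in graph_components(graph)) {
    sub <- igraph::induced_subgraph(graph, nodes)
    nc <- length(nodes)
    bw <- igraph::betweenness(sub, directed = FALSE, normalized = nc > 2)
    out[nodes] <- if (nc > 2) bw[igraph::V(sub)$name] else 0
  }
  out
}

#' Node centralities and graph-level topology summary
#'
#' Computes per-node degree, local clustering coefficient (0 for nodes of
#' degree < 2) and betweenness centrality (shortest-path counts with
#' fractional weighting of multiple shortest paths, normalized by
#' `(n-1)(n-2)/2` within the node's connected component), plus the
#' graph-level means. The mean shortest path and small-world index refer to
#' the largest connected component; the small-world index is `NA` for
#' graphs whose largest component has mean degree <= 1.
#'
#' @param graph an undirected `igraph`.
#' @return a `topology_summary`: list with `nodes` (data.frame `node`,
#'   `degree`, `clustering`, `betweenness`), `mean_degree`,
#'   `mean_clustering`, `mean_shortest_path`, `small_world_index`.
#' @export
node_centralities <- function(graph) {
  validate_mixed_graph(graph)
  deg <- igraph::degree(graph)
  cc <- .local_clustering(graph)
  bw <- .component_betweenness(graph)
  nodes <- data.frame(node = igraph::V(graph)$name, degree = as.integer(deg),
                      clustering = as.numeric(cc),
                      betweenness = as.numeric(bw), stringsAsFactors = FALSE)
  msp <- NA_real_
  swi <- NA_real_
  if (igraph::ecount(graph) > 0) {
    lc <- .largest_component(graph)
    msp <- average_shortest_path(graph, scope = "largest_component")
    kbar <- 2 * igraph::ecount(lc) / igraph::vcount(lc)
    if (kbar > 1 && igraph::vcount(lc) > 2)
      swi <- small_world_index(lc)
  }
  structure(list(nodes = nodes,
                 mean_degree = if (nrow(nodes)) 2 * igraph::ecount(graph) /
                   igraph::vcount(graph) else NA_real_,
                 mean_clustering = mean(nodes$clustering),
                 mean_shortest_path = msp,
                 small_world_index = swi),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("<topology_summary> %d nodes; mean degree %.2f; mean ",
                     "clustering %.3f;\n  mean shortest path %.3f; ",
                     "small-world index %.2f\n"),
              nrow(x$nodes), x$mean_degree, x$mean_clustering,
              x$mean_shortest_path, x$small_world_index))
  invisible(x)
}

#' Average shortest-path length
#'
#' Mean of pairwise shortest-path lengths over unordered node pairs, either
#' within the largest connected component or pooled over all components
#' (pairs in different components never contribute).
#'
#' @param graph an undirected `igraph` with at least one edge.
#' @param scope `"largest_component"` (default) or `"per_component"`.
#' @return a single numeric value.
#' @export
average_shortest_path <- function(graph, scope = c("largest_component",
                                                   "per_component")) {
  scope <- match.arg(scope)
  if (igraph::ecount(graph) == 0)
    stop("graph has no edges; average shortest path undefined")
  pooled_num <- 0; pooled_den <- 0
  comps <- graph_components(graph)
  for (k in seq_along(comps)) {
    nodes <- comps[[k]]
    if (length(nodes) < 2) next
    sub <- igraph::induced_subgraph(graph, nodes)
    d <- igraph::distances(sub)
    num <- sum(d[upper.tri(d)])
    den <- choose(length(nodes), 2)
    if (scope == "largest_component" && k == 1) return(num / den)
    pooled_num <- pooled_num + num
    pooled_den <- pooled_den + den
  }
  if (scope == "largest_component") stop("largest component has no edges")
  pooled_num / pooled_den
}

#' Per-node mean shortest-path length
#'
#' Mean graph distance from one node to every other node of its connected
#' component (the node itself excluded); the per-node counterpart of
#' [average_shortest_path()].
#'
#' @param graph an undirected `igraph`.
#' @param node node name.
#' @return numeric; `NA` for isolated nodes.
#' @export
node_average_shortest_path <- function(graph, node) {
  if (!(node %in% igraph::V(graph)$name)) stop("unknown node '", node, "'")
  d <- igraph::distances(graph, v = node)[1, ]
  d <- d[is.finite(d) & names(d) != node]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Small-world index
#'
#' `S = (C / C_rand) / (L / L_rand)` where `C` is the mean local clustering
#' coefficient, `L` the average shortest-path length, and `C_rand`,
#' `L_rand` the Erdos-Renyi expectations for a random graph with the same
#' number of nodes and edges: analytically `C_rand = kbar/n` and
#' `L_rand = ln(n)/ln(kbar)` with `kbar` the mean degree, or Monte-Carlo
#' averages over `m` sampled G(n, M) graphs. Values well above 1 indicate
#' small-world structure (high clustering, short paths).
#'
#' @param graph a connected undirected `igraph` with mean degree > 1.
#' @param mode `"analytic"` (default, deterministic) or `"montecarlo"`.
#' @param m random graphs to average in Monte-Carlo mode (default 50).
#' @param seed seed for Monte-Carlo mode.
#' @return a single numeric value.
#' @export
small_world_index <- function(graph, mode = c("analytic", "montecarlo"),
                              m = 50L, seed = 1L) {
  mode <- match.arg(mode)
  if (igraph::vcount(graph) < 3) stop("need at least 3 nodes")
  if (igraph::components(graph)$no != 1)
    stop("graph is disconnected; pass the largest component")
  n <- igraph::vcount(graph)
  nE <- igraph::ecount(graph)
  kbar <- 2 * nE / n
  if (kbar <= 1) stop("mean degree must exceed 1")
  C <- mean(.local_clustering(graph))
  L <- average_shortest_path(graph, scope = "largest_component")
  if (mode == "analytic") {
    C_rand <- kbar / n
    L_rand <- log(n) / log(kbar)
  } else {
    set.seed(seed)
    Cs <- Ls <- numeric(m)
    for (i in seq_len(m)) {
      gr <- igraph::sample_gnm(n, nE)
      Cs[i] <- mean(.local_clustering(gr))
      Ls[i] <- average_shortest_path(gr, scope = "per_component")
    }
    C_rand <- mean(Cs)
    L_rand <- mean(Ls)
  }
  (C / C_rand) / (L / L_rand)
}

#' Fraction of all shortest paths mediated by a node
#'
#' Unnormalized betweenness of the node (multiple shortest paths counted
#' fractionally) divided by the total number of shortest paths, i.e. the
#' number of connected unordered node pairs. By default adjacent pairs are
#' included in the denominator (their single-edge shortest path simply has
#' no interior vertex); `include_adjacent = FALSE` restricts the
#' denominator to non-adjacent connected pairs.
#'
#' @param graph an undirected `igraph`.
#' @param node node name.
#' @param include_adjacent include adjacent pairs in the denominator
#'   (default `TRUE`).
#' @return a fraction in \[0, 1\].
#' @export
mediation_fraction <- function(graph, node, include_adjacent = TRUE) {
  if (!(node %in% igraph::V(graph)$name)) stop("unknown node '", node, "'")
  raw <- igraph::betweenness(graph, v = node, directed = FALSE,
                             normalized = FALSE)
  comps <- graph_components(graph)
  total <- 0
  for (nodes in comps) {
    if (length(nodes) < 2) next
    npairs <- choose(length(nodes), 2)
    if (!include_adjacent) {
      sub <- igraph::induced_subgraph(graph, nodes)
      npairs <- npairs - igraph::ecount(sub)
    }
    total <- total + npairs
  }
  if (total == 0) return(0)
  as.numeric(raw) / total
}

#' Weighted network of all ever-selected edges
#'
#' Builds the graph containing every pair with positive selection
#' frequency; edge weights equal the frequencies. Thresholding this graph
#' at `tau` reproduces [threshold_edges()].
#'
#' @param table a `stability_table`.
#' @param nodes optional node universe (character vector or data.frame);
#'   defaults to the union of pair members.
#' @return an undirected weighted `igraph`.
#' @export
weighted_graph <- function(table, nodes = NULL) {
  keep <- table$frequency > 0
  tab <- table[keep, , drop = FALSE]
  if (is.null(nodes))
    nodes <- sort(unique(c(tab$var1, tab$var2)))
  edges <- if (nrow(tab)) data.frame(from = tab$var1, to = tab$var2,
                                     frequency = tab$frequency,
                                     weight = tab$frequency,
                                     stringsAsFactors = FALSE) else NULL
  mixed_graph(nodes, edges)
}
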