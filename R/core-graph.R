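#' Construct a mixed-graph network
#'
#' Networks are plain undirected [igraph][igraph::igraph-package] objects
#' whose vertices are variables (attributes `name`, `kind`, `layer`,
#' optionally `module`) and whose edges carry a selection `frequency` in
#' \[0, 1\] and a `sign` in `{"+", "-", "ambiguous"}`. This constructor
#' validates the invariants (unique names, no self-loops, at most one edge
#' per unordered pair, frequencies in range).
#'
#' @param nodes a `data.frame` with at least a `name` column; extra columns
#'   (`kind`, `layer`, `module`, ...) become vertex attributes. A character
#'   vector is accepted as shorthand for names only.
#' @param edges optional `data.frame` with columns `from`, `to` and optional
#'   `frequency`, `sign`, `weight` columns (extra columns become edge
#'   attributes).
#' @return an undirected `igraph` object.
#' @export
mixed_graph <- function(nodes, edges = NULL) {
  if (is.character(nodes)) nodes <- data.frame(name = nodes,
                                               stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name))
    stop("duplicate node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(nodes))
    for (cn in names(nodes)) g <- igraph::set_vertex_attr(g, cn,
                                                          value = nodes[[cn]])
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  validate_mixed_graph(g)
  g
}

#' Validate mixed-graph invariants
#'
#' Checks that a graph is undirected, simple (no self-loops, no duplicate
#' edges), has unique node names, and that any `frequency` edge attribute
#' lies in \[0, 1\].
#'
#' @param graph an `igraph` object.
#' @return invisibly, the graph; errors describe the violated invariant.
#' @export
validate_mixed_graph <- function(graph) {
  if (igraph::is_directed(graph))
    stop("mixed graphs are undirected; directed edges present")
  if (any(igraph::which_loop(graph)))
    stop("self-loop detected; mixed graphs must be simple")
  if (any(igraph::which_multiple(graph)))
    stop("duplicate edge for the same unordered pair")
  nm <- igraph::V(graph)$name
  if (is.null(nm) && igraph::vcount(graph) > 0)
    stop("nodes must be named")
  if (anyDuplicated(nm))
    stop("duplicate node names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  fr <- igraph::edge_attr(graph, "frequency")
  if (!is.null(fr) && is.numeric(fr) && any(!is.na(fr) & (fr < 0 | fr > 1)))
    stop("edge frequency outside [0, 1]")
  invisible(graph)
}

# Canonical attribute order for serialization: identity first, then the
# domain attributes, then anything else alphabetically.
.canonical_attrs <- function(present, preferred) {
  c(intersect(preferred, present), sort(setdiff(present, preferred)))
}

#' Write a network as graphml
#'
#' Serializes with a canonical attribute layout: vertex attributes in the
#' order name, kind, layer, module (then others alphabetically), edge
#' attributes frequency, sign, weight (then others). The `frequency`
#' attribute is written as a decimal string with 4 places so that
#' write-read-write round trips are byte-identical.
#'
#' @param graph an undirected `igraph` (validated).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mgm_graphml <- function(graph, path) {
  validate_mixed_graph(graph)
  g <- graph
  # format frequency to a stable decimal string
  if ("frequency" %in% igraph::edge_attr_names(g)) {
    fr <- igraph::E(g)$frequency
    g <- igraph::delete_edge_attr(g, "frequency")
    g <- igraph::set_edge_attr(g, "frequency", value = sprintf("%.4f", fr))
  }
  van <- .canonical_attrs(igraph::vertex_attr_names(g),
                          c("name", "kind", "layer", "module"))
  ean <- .canonical_attrs(igraph::edge_attr_names(g),
                          c("frequency", "sign", "weight"))
  # rebuild attributes in canonical creation order (igraph serializes in
  # creation order)
  vat <- lapply(van, function(a) igraph::vertex_attr(g, a))
  eat <- lapply(ean, function(a) igraph::edge_attr(g, a))
  for (a in igraph::vertex_attr_names(g)) g <- igraph::delete_vertex_attr(g, a)
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  for (i in seq_along(van)) g <- igraph::set_vertex_attr(g, van[i],
                                                         value = vat[[i]])
  for (i in seq_along(ean)) g <- igraph::set_edge_attr(g, ean[i],
                                                       value = eat[[i]])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network from graphml
#'
#' Reads a graphml file, rejects directed graphs, self-loops and duplicate
#' node ids, and converts the `frequency` edge attribute back to numeric.
#' Unknown attributes are preserved verbatim.
#'
#' @param path graphml file path.
#' @return an undirected `igraph` object.
#' @export
read_mgm_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g))
    stop("graphml at '", path, "' declares directed edges; ",
         "mixed graphical models are undirected")
  # igraph surfaces the structural graphml node ids as an "id" attribute;
  # node names are authoritative here and ids are regenerated on write
  if ("id" %in% igraph::vertex_attr_names(g) &&
      "name" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  if ("frequency" %in% igraph::edge_attr_names(g)) {
    fr <- igraph::E(g)$frequency
    if (is.character(fr)) {
      g <- igraph::delete_edge_attr(g, "frequency")
      g <- igraph::set_edge_attr(g, "frequency", value = as.numeric(fr))
    }
  }
  validate_mixed_graph(g)
  g
}

#' Canonical edge keys of a graph
#'
#' Returns each edge as the key `"a|b"` with the two node names sorted,
#' the representation used by stability tables and recovery metrics.
#'
#' @param graph an undirected `igraph`.
#' @return character vector, one key per edge.
#' @export
graph_edge_keys <- function(graph) {
  if (igraph::ecount(graph) == 0) return(character(0))
  el <- igraph::as_edgelist(graph, names = TRUE)
  pair_key(el[, 1], el[, 2])
}
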