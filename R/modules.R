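#' Modularity-based module detection
#'
#' Partitions the nodes into modules by maximizing Newman-Girvan
#' modularity. Three solvers are available: `exact` (a branch-and-bound
#' search over cluster assignments, provably maximal; limited to components
#' of at most 120 nodes and practical well below that), `greedy`
#' (deterministic fast-greedy agglomeration) and `spinglass` (seeded
#' stochastic optimization). Detection runs per connected component — for
#' modularity this is equivalent to a global search, since a module
#' spanning components can always be split without decreasing the score —
#' and singleton components form singleton modules.
#'
#' @param graph an undirected `igraph`.
#' @param method `"exact"`, `"greedy"` or `"spinglass"`.
#' @param seed integer seed (used by `spinglass`).
#' @return a `module_partition`: list with `membership` (named integer
#'   vector, labels 1..k) and `modularity` (the score of the partition on
#'   the full graph).
#' @export
detect_modules <- function(graph, method = c("exact", "greedy", "spinglass"),
                           seed = 1L) {
  method <- match.arg(method)
  validate_mixed_graph(graph)
  comps <- graph_components(graph)
  membership <- setNames(integer(igraph::vcount(graph)),
                         igraph::V(graph)$name)
  next_label <- 1L
  for (nodes in comps) {
    sub <- igraph::induced_subgraph(graph, nodes)
    if (length(nodes) == 1 || igraph::ecount(sub) == 0) {
      for (v in nodes) {
        membership[v] <- next_label
        next_label <- next_label + 1L
      }
      next
    }
    mem <- switch(method,
      greedy = {
        # cut the agglomeration dendrogram at the modularity-maximal number
        # of communities (preferring fewer modules on ties)
        cl <- igraph::cluster_fast_greedy(sub)
        best <- NULL; best_q <- -Inf
        for (kk in seq_len(igraph::vcount(sub))) {
          mk <- tryCatch(igraph::cut_at(cl, no = kk),
                         error = function(e) NULL)
          if (is.null(mk)) next
          qk <- igraph::modularity(sub, mk)
          if (qk > best_q + 1e-12) {
            best_q <- qk
            best <- mk
          }
        }
        setNames(best, igraph::V(sub)$name)
      },
      spinglass = {
        set.seed(derive_seed(seed, "spinglass", nodes[1]))
        cl <- igraph::cluster_spinglass(sub)
        igraph::membership(cl)
      },
      exact = {
        if (length(nodes) > 120)
          stop("exact modularity is limited to components of <= 120 nodes; ",
               "use method = 'greedy' or 'spinglass'")
        .exact_modularity(sub)
      })
    labs <- sort(unique(mem))
    for (l in labs) {
      membership[names(mem)[mem == l]] <- next_label
      next_label <- next_label + 1L
    }
  }
  Q <- modularity_score(graph, membership)
  structure(list(membership = membership, modularity = Q),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(unique(x$membership)), " modules over ",
      length(x$membership), " nodes; modularity ",
      sprintf("%.4f", x$modularity), "\n", sep = "")
  invisible(x)
}

#' Modularity of a given partition
#'
#' @param graph an undirected `igraph`.
#' @param membership named vector of module labels covering all nodes.
#' @return the Newman-Girvan modularity score.
#' @export
modularity_score <- function(graph, membership) {
  nm <- igraph::V(graph)$name
  if (!all(nm %in% names(membership)))
    stop("membership must cover every node")
  igraph::modularity(graph, as.integer(factor(membership[nm])))
}

# Exact maximum-modularity partition by depth-first branch and bound.
# Nodes are assigned one by one (decreasing-degree order) either to an
# already-open cluster or to a new one; the admissible bound adds, for every
# edge not yet internal-or-settled, its maximal possible modularity
# contribution max(0, (1 - k_i k_j / 2m) / m). Warm start: fast-greedy.
.exact_modularity <- function(sub) {
  n <- igraph::vcount(sub)
  m <- igraph::ecount(sub)
  A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  k <- igraph::degree(sub)
  ord <- order(-k, igraph::V(sub)$name)
  A <- A[ord, ord]
  k <- k[ord]
  nms <- igraph::V(sub)$name[ord]
  # pairwise modularity contribution if co-clustered (unordered pair)
  contrib <- (A - outer(k, k) / (2 * m)) / m
  diag(contrib) <- 0
  # suffix bound: positive contributions of pairs whose later node is > t
  pos_later <- numeric(n)
  for (s in 2:n)
    pos_later[s] <- sum(pmax(0, contrib[seq_len(s - 1), s]))
  suffix <- rev(cumsum(rev(pos_later)))  # suffix[t] = sum over s >= t
  suffix <- c(suffix[-1], 0)             # pairs with later node > t
  gr <- igraph::cluster_fast_greedy(sub)
  gmem <- igraph::membership(gr)[nms]
  best_Q <- igraph::modularity(sub, as.integer(factor(
    igraph::membership(gr))))
  best_assign <- as.integer(factor(gmem))
  assign <- integer(n)
  rec <- function(t, Q, n_open) {
    if (t > n) {
      if (Q > best_Q + 1e-12) {
        best_Q <<- Q
        best_assign <<- assign[seq_len(n)]
      }
      return(invisible(NULL))
    }
    if (Q + suffix[t - 1] <= best_Q + 1e-12 && t > 1) return(invisible(NULL))
    upper <- min(n_open + 1L, t)
    for (c in seq_len(upper)) {
      same <- which(assign[seq_len(t - 1)] == c)
      dQ <- if (length(same)) sum(contrib[same, t]) else 0
      assign[t] <<- c
      rec(t + 1L, Q + dQ, max(n_open, c))
    }
    assign[t] <<- 0L
    invisible(NULL)
  }
  # handle t = 1 bound edge case by starting the recursion directly
  assign[1] <- 1L
  rec(2L, 0, 1L)
  setNames(best_assign, nms)
}
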