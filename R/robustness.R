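#' Edge-inclusion cutoff sweep
#'
#' Re-thresholds a stability table at a series of cutoffs (defaults 20%,
#' 40%, 60%, 80%, 100% of the half-sample models). Cutoffs below 1 use the
#' strict "more than" rule of [threshold_edges()]; the 100% cutoff uses
#' `>=` so that always-selected edges form a non-empty top graph. The
#' resulting graphs are nested along increasing cutoffs.
#'
#' @param table a `stability_table`.
#' @param cutoffs numeric vector in (0, 1\].
#' @param nodes optional node universe for the graphs (defaults to all
#'   variables appearing in `table`).
#' @return named list (cutoff -> `igraph`).
#' @export
cutoff_sweep <- function(table, cutoffs = c(0.2, 0.4, 0.6, 0.8, 1.0),
                         nodes = NULL) {
  stopifnot(all(cutoffs > 0), all(cutoffs <= 1))
  if (is.null(nodes)) nodes <- sort(unique(c(table$var1, table$var2)))
  out <- vector("list", length(cutoffs))
  names(out) <- format(cutoffs)
  for (i in seq_along(cutoffs)) {
    cut <- cutoffs[i]
    keys <- threshold_edges(table, tau = cut, strict = cut < 1)
    edges <- if (length(keys)) {
      ep <- split_pair_key(keys)
      freq <- setNames(table$frequency, pair_key(table$var1, table$var2))
      data.frame(from = ep$var1, to = ep$var2,
                 frequency = as.numeric(freq[keys]),
                 stringsAsFactors = FALSE)
    } else NULL
    out[[i]] <- mixed_graph(data.frame(name = nodes,
                                       stringsAsFactors = FALSE), edges)
  }
  out
}

#' Correlation of node centralities between two networks
#'
#' Rank (Spearman, default) or Pearson correlation of node degrees and of
#' local clustering coefficients across the shared nodes of two graphs;
#' used to quantify how stable centralities are across edge cutoffs.
#'
#' @param graph_a,graph_b undirected `igraph`s over a shared node universe.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return named numeric vector `c(degree = ..., clustering = ...)`; `NA`
#'   entries when a centrality is constant in either graph.
#' @export
centrality_correlation <- function(graph_a, graph_b,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(igraph::V(graph_a)$name, igraph::V(graph_b)$name)
  if (length(shared) < 3)
    stop("need at least 3 shared nodes (found ", length(shared), ")")
  da <- igraph::degree(graph_a)[shared]
  db <- igraph::degree(graph_b)[shared]
  ca <- .local_clustering(graph_a)[shared]
  cb <- .local_clustering(graph_b)[shared]
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  }
  c(degree = safe_cor(da, db), clustering = safe_cor(ca, cb))
}

.membership_of <- function(p) {
  if (inherits(p, "module_partition")) p$membership else p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table: `(Index - E[Index]) / (Max - E[Index])`. Equals 1 for identical
#' partitions up to relabeling and has expectation 0 under random
#' partitions with the same cluster sizes. When both partitions are the
#' same trivial partition (a single cluster, or all singletons) the
#' adjustment denominator vanishes and 1 is returned.
#'
#' @param p1,p2 `module_partition`s or named label vectors over the same
#'   node set.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p1, p2) {
  m1 <- .membership_of(p1)
  m2 <- .membership_of(p2)
  if (!setequal(names(m1), names(m2)))
    stop("partitions cover different node sets")
  m2 <- m2[names(m1)]
  tab <- table(m1, m2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * total)
    return(1)  # identical trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Null distribution of the adjusted Rand index
#'
#' Draws `n_draws` random relabelings of the reference partition that
#' preserve its module sizes (node labels permuted) and returns the ARI of
#' each draw against the reference; the mean is close to 0 by construction
#' of the adjustment. With `size_preserving = FALSE` each node instead gets
#' a uniformly random module label.
#'
#' @param reference a `module_partition` or named label vector.
#' @param n_draws number of random partitions (default 1000).
#' @param seed integer seed.
#' @param size_preserving permute labels (default) or draw uniform labels.
#' @return numeric vector of length `n_draws`.
#' @export
ari_background <- function(reference, n_draws = 1000L, seed = 1L,
                           size_preserving = TRUE) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  mem <- .membership_of(reference)
  if (length(unique(mem)) == 1) {
    warning("reference has a single module; all background draws are ",
            "identical to it (ARI 1)")
    return(rep(1, n_draws))
  }
  set.seed(derive_seed(seed, "ari_background"))
  vapply(seq_len(n_draws), function(i) {
    draw <- if (size_preserving) setNames(sample(mem), names(mem))
            else setNames(sample(unique(mem), length(mem), replace = TRUE),
                          names(mem))
    adjusted_rand_index(mem, draw)
  }, 0)
}

#' Twin-split replication of the inferred network
#'
#' Splits the samples into two disjoint datasets containing the first and
#' the second member of each two-member family respectively (singleton
#' families are distributed randomly across the halves), infers a model on
#' each half, and reports how much of a reference model's edge set the
#' union of the two split models recovers.
#'
#' @param dataset complete [mixed_dataset()] with family ids; families may
#'   have at most 2 members.
#' @param config an [inference_config()] used for both split models.
#' @param reference an `igraph` reference model (e.g. from the full data).
#' @param seed seed for the singleton assignment.
#' @return list with `graph1`, `graph2`, `split_overlap` (fraction of
#'   reference edges present in the union), `unique_to_reference` (count of
#'   reference edges absent from both).
#' @export
split_half_models <- function(dataset, config, reference, seed = 1L) {
  fam <- split(seq_along(dataset$family_ids), dataset$family_ids)
  sizes <- lengths(fam)
  if (any(sizes > 2))
    stop("family with more than 2 members: ",
         paste(names(sizes)[sizes > 2], collapse = ", "))
  first <- integer(0); second <- integer(0)
  for (members in fam[sizes == 2]) {
    first <- c(first, members[1])
    second <- c(second, members[2])
  }
  singles <- unlist(fam[sizes == 1], use.names = FALSE)
  if (length(singles)) {
    set.seed(derive_seed(seed, "twin_split"))
    singles <- sample(singles)
    half <- floor(length(singles) / 2)
    first <- c(first, singles[seq_len(half)])
    if (length(singles) > half) second <- c(second,
                                            singles[(half + 1):length(singles)])
  }
  d1 <- subset_dataset(dataset, samples = sort(first))
  d2 <- subset_dataset(dataset, samples = sort(second))
  fit1 <- infer_mgm(d1, config)
  fit2 <- infer_mgm(d2, config)
  ref_edges <- graph_edge_keys(reference)
  union_edges <- union(graph_edge_keys(fit1$graph),
                       graph_edge_keys(fit2$graph))
  overlap <- if (length(ref_edges))
    mean(ref_edges %in% union_edges) else NA_real_
  list(graph1 = fit1$graph, graph2 = fit2$graph,
       split_overlap = overlap,
       unique_to_reference = sum(!(ref_edges %in% union_edges)))
}

#' Restrict an enlarged network and compare its modules
#'
#' Takes the induced subgraph of a larger model on a node subset (e.g. the
#' nodes of the original model), re-detects modules on it and returns the
#' adjusted Rand index against a reference partition over the same nodes.
#'
#' @param large_graph an undirected `igraph`.
#' @param node_subset character vector of node names (subset of the graph).
#' @param reference_partition `module_partition` or named labels covering
#'   `node_subset`.
#' @param method module-detection method (default `"greedy"`).
#' @param seed seed for stochastic detection.
#' @return list with `graph` (the induced subgraph), `partition` (detected
#'   modules) and `ari`.
#' @export
restrict_and_compare <- function(large_graph, node_subset,
                                 reference_partition, method = "greedy",
                                 seed = 1L) {
  missing <- setdiff(node_subset, igraph::V(large_graph)$name)
  if (length(missing))
    stop("nodes not in graph: ", paste(missing, collapse = ", "))
  sub <- igraph::induced_subgraph(large_graph, node_subset)
  part <- detect_modules(sub, method = method, seed = seed)
  ref <- .membership_of(reference_partition)[node_subset]
  ari <- adjusted_rand_index(part$membership, setNames(ref, node_subset))
  list(graph = sub, partition = part, ari = ari)
}

#' Full stability report
#'
#' Convenience wrapper running the cutoff sweep, centrality correlations
#' and module-assignment comparisons (ARI of each cutoff graph's modules
#' against the reference partition, plus the size-preserving random
#' background).
#'
#' @param table a `stability_table`.
#' @param reference reference `igraph` model (the default-threshold graph).
#' @param cutoffs cutoff vector (default `c(0.2, 0.4, 0.6, 0.8, 1)`).
#' @param n_draws background draws (default 1000).
#' @param method module-detection method for the comparisons.
#' @param seed integer seed.
#' @return a `stability_report` list: `per_cutoff` data.frame (`cutoff`,
#'   `n_edges`, `degree_cor`, `clustering_cor`, `ari`), `background_ari`
#'   numeric vector.
#' @export
stability_report <- function(table, reference,
                             cutoffs = c(0.2, 0.4, 0.6, 0.8, 1.0),
                             n_draws = 1000L, method = "greedy", seed = 1L) {
  nodes <- igraph::V(reference)$name
  sweep <- cutoff_sweep(table, cutoffs, nodes = nodes)
  ref_part <- detect_modules(reference, method = method, seed = seed)
  rows <- lapply(seq_along(cutoffs), function(i) {
    g <- sweep[[i]]
    cc <- tryCatch(centrality_correlation(reference, g),
                   error = function(e) c(degree = NA_real_,
                                         clustering = NA_real_))
    part <- detect_modules(g, method = method, seed = seed)
    data.frame(cutoff = cutoffs[i], n_edges = igraph::ecount(g),
               degree_cor = cc[["degree"]],
               clustering_cor = cc[["clustering"]],
               ari = adjusted_rand_index(ref_part, part))
  })
  structure(list(per_cutoff = do.call(rbind, rows),
                 background_ari = ari_background(ref_part, n_draws = n_draws,
                                                 seed = seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  print(x$per_cutoff, row.names = FALSE)
  cat(sprintf("background ARI: mean %.4f over %d draws\n",
              mean(x$background_ari), length(x$background_ari)))
  invisible(x)
}
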