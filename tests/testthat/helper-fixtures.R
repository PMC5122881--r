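# Shared fixtures and independent oracles used across the test files.

# --- dataset builders -------------------------------------------------------

# small fully typed dataset: 2 continuous, 1 binary, 1 categorical
tiny_dataset <- function(n = 6, seed = 42) {
  set.seed(seed)
  values <- data.frame(
    height = rnorm(n, 170, 10),
    weight = rnorm(n, 70, 8),
    smoker = rbinom(n, 1, 0.4),
    diet = sample(c("low", "med", "high"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  vars <- variable_spec(
    c("height", "weight", "smoker", "diet"),
    c("continuous", "continuous", "binary", "categorical"),
    c("dxa", "dxa", "phenotype", "phenotype"),
    list(NULL, NULL, NULL, c("low", "med", "high")))
  mixed_dataset(values, vars,
                family_ids = rep(paste0("f", seq_len(ceiling(n / 2))),
                                 each = 2)[seq_len(n)])
}

# random mixed dataset with missingness, for round-trip tests
random_dataset <- function(n = 10, p_cont = 4, p_bin = 2, p_cat = 2,
                           miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- p_cont + p_bin + p_cat
  nms <- sprintf("x%02d", seq_len(p))
  kinds <- c(rep("continuous", p_cont), rep("binary", p_bin),
             rep("categorical", p_cat))
  levels <- lapply(kinds, function(k)
    if (k == "categorical") c("a", "b", "c") else NULL)
  values <- as.data.frame(lapply(seq_len(p), function(j) {
    if (kinds[j] == "continuous") rnorm(n)
    else if (kinds[j] == "binary") rbinom(n, 1, 0.5)
    else sample(c("a", "b", "c"), n, replace = TRUE)
  }), stringsAsFactors = FALSE)
  names(values) <- nms
  for (j in seq_len(p)) values[runif(n) < miss, j] <- NA
  mixed_dataset(values, variable_spec(nms, kinds, "phenotype", levels))
}

# complete dataset ready for inference (continuous only)
complete_dataset <- function(X) {
  nms <- colnames(X)
  mixed_dataset(as.data.frame(X), variable_spec(nms, "continuous",
                                                "metabolomics"))
}

# permute rows and columns of a dataset (new object, same content)
subset_dataset_for_test <- function(ds, sample_perm, var_perm) {
  vars <- ds$variables[var_perm, , drop = FALSE]
  rownames(vars) <- NULL
  mixed_dataset(ds$values[sample_perm, var_perm, drop = FALSE], vars,
                sample_ids = ds$sample_ids[sample_perm],
                family_ids = ds$family_ids[sample_perm])
}

# --- graph builders ---------------------------------------------------------

graph_from_edges <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(unlist(edges)))
  ed <- if (length(edges))
    data.frame(from = vapply(edges, `[`, "", 1),
               to = vapply(edges, `[`, "", 2), stringsAsFactors = FALSE)
  else NULL
  mixed_graph(data.frame(name = nodes, stringsAsFactors = FALSE), ed)
}

# --- independent oracles ----------------------------------------------------

# all set partitions of a vector (Bell-number enumeration)
all_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_partitions(items[-1])
  out <- list()
  for (part in rest) {
    for (k in seq_along(part)) {
      grown <- part
      grown[[k]] <- c(items[1], grown[[k]])
      out[[length(out) + 1]] <- grown
    }
    out[[length(out) + 1]] <- c(list(items[1]), part)
  }
  out
}

# brute-force maximum modularity by exhaustive partition search
brute_force_modularity <- function(graph) {
  nms <- igraph::V(graph)$name
  best <- -Inf
  for (part in all_partitions(nms)) {
    mem <- integer(length(nms))
    names(mem) <- nms
    for (k in seq_along(part)) mem[part[[k]]] <- k
    q <- modularity_score(graph, mem)
    if (q > best) best <- q
  }
  best
}

# brute-force ARI by counting agreements over all element pairs
brute_force_ari <- function(m1, m2) {
  m2 <- m2[names(m1)]
  pairs <- combn(names(m1), 2)
  same1 <- m1[pairs[1, ]] == m1[pairs[2, ]]
  same2 <- m2[pairs[1, ]] == m2[pairs[2, ]]
  a <- sum(same1 & same2)          # together in both
  d <- sum(!same1 & !same2)        # apart in both
  n_pairs <- ncol(pairs)
  b <- sum(same1 & !same2)
  c_ <- sum(!same1 & same2)
  expected <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n_pairs
  max_index <- n_pairs
  ((a + d) - expected) / (max_index - expected)
}

# BFS single-source shortest-path distances and path counts (sigma)
bfs_oracle <- function(adj, source) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[source] <- 0; sigma[source] <- 1
  frontier <- source
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# fractional betweenness of every node by explicit path counting:
# sum over pairs (s,t) of sigma_st(v) / sigma_st
betweenness_oracle <- function(graph) {
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  n <- nrow(adj)
  nms <- igraph::V(graph)$name
  bw <- setNames(numeric(n), nms)
  bfs <- lapply(seq_len(n), function(s) bfs_oracle(adj, s))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(bfs[[s]]$dist[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      # v interior on an s-t geodesic iff distances add up
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == bfs[[s]]$dist[t]) {
        bw[v] <- bw[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] /
          bfs[[s]]$sigma[t]
      }
    }
  }
  bw
}

# mean shortest path within components by BFS
asp_oracle <- function(graph) {
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  n <- nrow(adj)
  total <- 0; count <- 0
  for (s in seq_len(n - 1)) {
    d <- bfs_oracle(adj, s)$dist
    for (t in (s + 1):n) if (is.finite(d[t])) {
      total <- total + d[t]; count <- count + 1
    }
  }
  total / count
}
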