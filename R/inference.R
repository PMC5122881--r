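#' Inference configuration
#'
#' Collects the tuning parameters of the random-forest graphical model
#' estimator.
#'
#' @param B number of complementary half-sample pairs (default 100, i.e.
#'   200 half-sample models).
#' @param q number of top-ranked pairs kept as edges in each half-sample
#'   model. `NULL` (default) selects `ceiling(sqrt(alpha * (2*tau - 1) * P))`
#'   with `P` the number of candidate pairs — the value at which the
#'   stability-selection bound on the expected number of falsely selected
#'   edges is about `alpha`.
#' @param tau selection-frequency threshold in (0.5, 1\] (default 0.8:
#'   edges present in more than 80% of half-sample models are kept).
#' @param alpha target expected false-selection level used by the automatic
#'   `q` rule (default 0.05).
#' @param rf_trees trees per forest (default 500).
#' @param rf_importance `"permutation"` (default) or `"impurity"`.
#' @param rf_mtry predictors tried per split; `NULL` (default) uses
#'   `ceiling(p/3)` for regression targets and `ceiling(sqrt(p))` for
#'   classification targets, `p` being the predictor count.
#' @param cpss_mode `"frequency"` (default; selection frequency over all 2B
#'   half-sample models) or `"both_halves"` (fraction of the B pairs where
#'   the edge appears in both halves).
#' @param seed integer base seed; per-(subsample, target) seeds are derived
#'   from it by name hashing, making results invariant to row and column
#'   order.
#' @return an `inference_config` list.
#' @export
inference_config <- function(B = 100L, q = NULL, tau = 0.8, alpha = 0.05,
                             rf_trees = 500L, rf_importance = c("permutation",
                                                                "impurity"),
                             rf_mtry = NULL,
                             cpss_mode = c("frequency", "both_halves"),
                             seed = 1L) {
  rf_importance <- match.arg(rf_importance)
  cpss_mode <- match.arg(cpss_mode)
  if (B < 1) stop("B must be >= 1")
  if (tau <= 0.5 || tau > 1) stop("tau must lie in (0.5, 1]")
  if (!is.null(q) && q < 1) stop("q must be >= 1")
  structure(list(B = as.integer(B), q = q, tau = tau, alpha = alpha,
                 rf_trees = as.integer(rf_trees),
                 rf_importance = rf_importance, rf_mtry = rf_mtry,
                 cpss_mode = cpss_mode, seed = as.integer(seed)),
            class = "inference_config")
}

# Automatic q: expected-false-selection bound q^2 / ((2 tau - 1) P) ~ alpha.
default_q <- function(n_pairs, tau, alpha = 0.05) {
  max(1L, as.integer(ceiling(sqrt(alpha * (2 * tau - 1) * n_pairs))))
}

#' Complementary-pairs subsampling plan
#'
#' Draws `B` random partitions of the samples into two disjoint halves of
#' sizes `floor(n/2)` and `ceiling(n/2)`; each partition contributes two
#' half-sample model fits, giving `2B` models in total.
#'
#' @param n_samples number of samples (>= 4).
#' @param B number of complementary pairs.
#' @param seed integer seed; the plan is reproducible.
#' @return a `subsample_plan`: list of `B` lists with integer index vectors
#'   `first` and `second`.
#' @export
make_subsample_plan <- function(n_samples, B, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  if (n_samples < 4) stop("need at least 4 samples")
  pairs <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, "subsample", b))
    perm <- sample.int(n_samples)
    h <- floor(n_samples / 2)
    pairs[[b]] <- list(first = sort(perm[seq_len(h)]),
                       second = sort(perm[(h + 1):n_samples]))
  }
  structure(list(pairs = pairs, n_samples = n_samples,
                 seed = as.integer(seed)), class = "subsample_plan")
}

# Model frame for the forests: variables in canonical (alphabetical) name
# order, categorical variables as factors.
.forest_frame <- function(dataset) {
  ord <- order(dataset$variables$name)
  vars <- dataset$variables[ord, , drop = FALSE]
  df <- dataset$values[, vars$name, drop = FALSE]
  for (j in seq_len(nrow(vars)))
    if (vars$kind[j] == "categorical")
      df[[j]] <- factor(df[[j]], levels = vars$levels[[j]])
  list(frame = df, vars = vars)
}

#' Random-forest importance matrix for one subsample
#'
#' For every variable one forest predicts it from all remaining variables
#' (regression for continuous targets, classification for binary and
#' categorical ones); row `i` of the result holds the importances of all
#' predictors for target `i`. Forest seeds are derived from
#' `(config$seed, subsample_index, target name)`, so the matrix is
#' invariant to row and column order of the input. A classification target
#' that is constant within the subsample yields an all-`NA` row (treated as
#' worst ranks downstream) with a warning.
#'
#' @param dataset a complete [mixed_dataset()] (typically a half-sample).
#' @param config an [inference_config()].
#' @param subsample_index integer label of the half-sample model (seeds).
#' @return a `p x p` numeric matrix with `NA` diagonal, dimnames = variable
#'   names in canonical order.
#' @export
importance_matrix <- function(dataset, config, subsample_index = 1L) {
  if (!all(dataset$observed)) stop("dataset must be complete (impute first)")
  ff <- .forest_frame(dataset)
  df <- ff$frame
  vars <- ff$vars
  p <- nrow(vars)
  M <- matrix(NA_real_, p, p, dimnames = list(vars$name, vars$name))
  for (i in seq_len(p)) {
    target <- vars$name[i]
    y <- df[[target]]
    classify <- vars$kind[i] != "continuous"
    if (classify) {
      y <- droplevels(factor(y))
      if (nlevels(y) < 2) {
        warning("target '", target, "' constant in subsample ",
                subsample_index, "; row set to minimal importance")
        next
      }
    }
    x <- df[, -i, drop = FALSE]
    npred <- ncol(x)
    mtry <- config$rf_mtry %||%
      if (classify) ceiling(sqrt(npred)) else ceiling(npred / 3)
    fit <- ranger::ranger(
      x = x, y = y,
      num.trees = config$rf_trees, importance = config$rf_importance,
      mtry = min(mtry, npred), respect.unordered.factors = "order",
      num.threads = 1,
      seed = derive_seed(config$seed, "forest", subsample_index, target))
    imp <- fit$variable.importance
    M[i, names(imp)] <- imp
  }
  M
}

#' Rank variable pairs by their worse directional rank
#'
#' Within each target row the predictors are ranked 1 (largest importance)
#' to `p - 1`; ties — including all-`NA` degenerate rows — share their worst
#' (maximum) rank. Each unordered pair receives the maximum of its two
#' directional ranks, and the pairs are ordered by (pair rank, sum of the
#' two directional ranks, lexicographic pair name).
#'
#' @param M importance matrix from [importance_matrix()].
#' @return a `data.frame` ordered best-first with columns `var1`, `var2`,
#'   `max_rank`, `sum_rank`.
#' @export
rank_pairs <- function(M) {
  p <- nrow(M)
  if (p < 2) stop("need at least 2 variables")
  nms <- rownames(M)
  R <- matrix(NA_real_, p, p, dimnames = dimnames(M))
  for (i in seq_len(p)) {
    imp <- M[i, -i]
    imp[is.na(imp)] <- -Inf
    R[i, -i] <- rank(-imp, ties.method = "max")
  }
  idx <- which(upper.tri(R), arr.ind = TRUE)
  a <- nms[idx[, 1]]; b <- nms[idx[, 2]]
  max_rank <- pmax(R[idx], R[idx[, c(2, 1), drop = FALSE]])
  sum_rank <- R[idx] + R[idx[, c(2, 1), drop = FALSE]]
  out <- data.frame(var1 = pmin(a, b), var2 = pmax(a, b),
                    max_rank = max_rank, sum_rank = sum_rank,
                    stringsAsFactors = FALSE)
  out[order(out$max_rank, out$sum_rank, out$var1, out$var2), , drop = FALSE]
}

#' Keep the q best-ranked pairs
#'
#' @param ranking output of [rank_pairs()].
#' @param q number of pairs to keep (1 <= q <= number of pairs).
#' @return character vector of pair keys (`"a|b"`, names sorted within
#'   pair).
#' @export
select_top_q <- function(ranking, q) {
  if (q > nrow(ranking)) stop("q = ", q, " exceeds the ", nrow(ranking),
                              " candidate pairs")
  if (q < 1) stop("q must be >= 1")
  head <- ranking[seq_len(q), , drop = FALSE]
  pair_key(head$var1, head$var2)
}

#' Aggregate per-subsample edge sets into selection frequencies
#'
#' @param edge_sets list of character vectors of pair keys, one per
#'   half-sample model (length `2B`).
#' @return a `stability_table`: data.frame (`var1`, `var2`, `frequency`)
#'   with attribute `n_subsamples`; frequencies are multiples of
#'   `1/length(edge_sets)`.
#' @export
aggregate_stability <- function(edge_sets) {
  n_sub <- length(edge_sets)
  counts <- table(unlist(edge_sets))
  if (length(counts) == 0) {
    tab <- data.frame(var1 = character(0), var2 = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
  } else {
    keys <- sort(names(counts))
    tab <- split_pair_key(keys)
    tab$frequency <- as.numeric(counts[keys]) / n_sub
  }
  structure(tab, n_subsamples = n_sub, class = c("stability_table",
                                                 "data.frame"))
}

#' Threshold a stability table into an edge set
#'
#' @param table a `stability_table`.
#' @param tau frequency threshold in (0, 1\].
#' @param strict keep edges with frequency strictly greater than `tau`
#'   (default, the "more than" reading); `FALSE` uses `>=`.
#' @return character vector of pair keys.
#' @export
threshold_edges <- function(table, tau = 0.8, strict = TRUE) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  keep <- if (strict) table$frequency > tau else table$frequency >= tau
  pair_key(table$var1[keep], table$var2[keep])
}

#' Estimate edge signs from full regressions
#'
#' Forest importances carry no sign, so for each retained edge `{x, y}` the
#' sign is read off two multiple regressions: `x` on all other variables and
#' `y` on all other variables (linear model for continuous responses,
#' logistic for binary). If the two partner coefficients agree in sign the
#' edge is `"+"` or `"-"`, otherwise `"ambiguous"`. Meta-layer variables are
#' excluded. When the design is singular (more predictors than samples) the
#' marginal correlation sign is used instead, with a warning.
#'
#' @param dataset complete [mixed_dataset()] (all samples).
#' @param edges character vector of pair keys.
#' @return named character vector (pair key -> sign).
#' @export
estimate_signs <- function(dataset, edges) {
  if (length(edges) == 0) return(setNames(character(0), character(0)))
  vars <- dataset$variables
  use <- vars$layer != "meta"
  vars <- vars[use, , drop = FALSE]
  X <- as.matrix(dataset$values[, vars$name, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  fallback <- p >= n
  if (fallback)
    warning("singular design (p >= n); falling back to marginal signs")
  coef_of <- function(target, partner) {
    y <- X[, target]
    Z <- X[, setdiff(colnames(X), target), drop = FALSE]
    if (vars$kind[vars$name == target] == "binary") {
      fit <- suppressWarnings(glm(y ~ Z, family = binomial()))
    } else fit <- lm(y ~ Z)
    cf <- coef(fit)[paste0("Z", partner)]
    unname(cf)
  }
  cache <- new.env(parent = emptyenv())
  get_coef <- function(target, partner) {
    key <- paste(target, partner, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- if (fallback) NA_real_ else coef_of(target, partner)
    cache[[key]] <- v
    v
  }
  out <- character(length(edges))
  names(out) <- edges
  pairs <- split_pair_key(edges)
  for (e in seq_along(edges)) {
    a <- pairs$var1[e]; b <- pairs$var2[e]
    if (!(a %in% colnames(X)) || !(b %in% colnames(X))) {
      out[e] <- "ambiguous"; next
    }
    c1 <- get_coef(a, b); c2 <- get_coef(b, a)
    if (is.na(c1) || is.na(c2)) {
      m <- cor(X[, a], X[, b])
      out[e] <- if (is.na(m) || m == 0) "ambiguous" else
        if (m > 0) "+" else "-"
    } else if (sign(c1) == sign(c2) && sign(c1) != 0) {
      out[e] <- if (c1 > 0) "+" else "-"
    } else out[e] <- "ambiguous"
  }
  out
}

#' Infer a mixed graphical model
#'
#' Full estimator: draw `B` complementary half-sample pairs, fit per-variable
#' forests on each of the `2B` halves, rank variable pairs by their worse
#' directional importance rank, keep the top `q` pairs per half-sample model,
#' aggregate selection frequencies, and keep edges whose frequency exceeds
#' `tau`. Edge signs come from full-sample regressions. If a `meta`-layer
#' family variable is present it takes part in every forest (absorbing
#' family-shared variation) but its node and incident edges are removed from
#' the returned graph and table.
#'
#' @param dataset complete, transformed [mixed_dataset()].
#' @param config an [inference_config()].
#' @return list with `graph` (an `igraph`; edges carry `frequency` and
#'   `sign`), `stability` (the full `stability_table`), and `q` (the value
#'   actually used).
#' @export
infer_mgm <- function(dataset, config = inference_config()) {
  if (!all(dataset$observed)) stop("dataset must be complete (impute first)")
  n <- n_samples(dataset)
  p <- n_variables(dataset)
  if (p < 2) stop("need at least 2 variables")
  n_pairs <- choose(p, 2)
  q <- config$q %||% default_q(n_pairs, config$tau, config$alpha)
  # canonical sample order: sorted ids, so results ignore row order
  ds <- subset_dataset(dataset, samples = order(dataset$sample_ids))
  plan <- make_subsample_plan(n, config$B, seed = derive_seed(config$seed,
                                                              "plan"))
  edge_sets <- vector("list", 2L * config$B)
  pair_hits <- new.env(parent = emptyenv())
  for (b in seq_len(config$B)) {
    halves <- plan$pairs[[b]]
    for (h in 1:2) {
      idx <- if (h == 1) halves$first else halves$second
      sub <- subset_dataset(ds, samples = idx)
      M <- importance_matrix(sub, config,
                             subsample_index = 2L * (b - 1L) + h)
      ranking <- rank_pairs(M)
      edge_sets[[2L * (b - 1L) + h]] <- select_top_q(ranking, q)
    }
  }
  stability <- aggregate_stability(edge_sets)
  if (config$cpss_mode == "frequency") {
    edges <- threshold_edges(stability, tau = config$tau)
  } else {
    both <- table(unlist(lapply(seq_len(config$B), function(b)
      intersect(edge_sets[[2L * b - 1L]], edge_sets[[2L * b]]))))
    frac <- as.numeric(both) / config$B
    edges <- names(both)[frac > config$tau]
  }
  # drop the family meta node from the reported model
  meta_vars <- dataset$variables$name[dataset$variables$layer == "meta"]
  if (length(meta_vars)) {
    pairs <- split_pair_key(edges)
    edges <- edges[!(pairs$var1 %in% meta_vars | pairs$var2 %in% meta_vars)]
    spairs <- stability[, c("var1", "var2")]
    keep <- !(spairs$var1 %in% meta_vars | spairs$var2 %in% meta_vars)
    stability <- structure(stability[keep, , drop = FALSE],
                           n_subsamples = attr(stability, "n_subsamples"),
                           class = class(stability))
  }
  signs <- estimate_signs(ds, edges)
  nodes <- dataset$variables[!(dataset$variables$name %in% meta_vars),
                             c("name", "kind", "layer")]
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  freq_lookup <- setNames(stability$frequency,
                          pair_key(stability$var1, stability$var2))
  edf <- if (length(edges)) {
    ep <- split_pair_key(edges)
    data.frame(from = ep$var1, to = ep$var2,
               frequency = as.numeric(freq_lookup[edges]),
               sign = as.character(signs[edges]), stringsAsFactors = FALSE)
  } else NULL
  graph <- mixed_graph(nodes, edf)
  list(graph = graph, stability = stability, q = q)
}
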