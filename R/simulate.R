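#' Simulation configuration
#'
#' Parameters of the synthetic mixed-type data generator. The defaults
#' emulate the study conditions the package is designed for: 510 samples
#' (178 twin pairs plus 154 singletons, i.e. 332 families) and 145 mixed
#' variables in a modular sparse dependence structure with moderate
#' missingness.
#'
#' @param n_samples number of samples (default 510).
#' @param n_continuous,n_binary variable counts (defaults 115 and 30).
#' @param structure `"chain"`, `"modular_blocks"` or `"random_sparse"`.
#' @param rho target partial correlation per edge, |rho| in (0, 1)
#'   (default 0.3).
#' @param missing_rate completely-at-random missingness in \[0, 0.2\]
#'   (default 0.05).
#' @param n_families number of families; `n_samples - n_families` of them
#'   are twin pairs, the rest singletons (default 332).
#' @param n_blocks blocks for `modular_blocks` (must divide the number of
#'   variables; default 5).
#' @param density edge probability for `random_sparse` (default 0.05).
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 510L, n_continuous = 115L,
                              n_binary = 30L,
                              structure = c("modular_blocks", "chain",
                                            "random_sparse"),
                              rho = 0.3, missing_rate = 0.05,
                              n_families = 332L, n_blocks = 5L,
                              density = 0.05, seed = 1L) {
  structure <- match.arg(structure)
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must lie in [0, 0.2]")
  if (abs(rho) <= 0 || abs(rho) >= 1) stop("|rho| must lie in (0, 1)")
  if (n_families > n_samples) stop("n_families cannot exceed n_samples")
  if (2 * n_families < n_samples)
    stop("too few families: pairs-and-singletons need n_families >= n_samples/2")
  base::structure(list(n_samples = as.integer(n_samples),
                       n_continuous = as.integer(n_continuous),
                       n_binary = as.integer(n_binary),
                       structure = structure, rho = rho,
                       missing_rate = missing_rate,
                       n_families = as.integer(n_families),
                       n_blocks = as.integer(n_blocks), density = density,
                       seed = as.integer(seed)), class = "simulation_config")
}

#' Ground-truth conditional-dependence graph
#'
#' Builds the sparse graph whose edges define the nonzero partial
#' correlations of the simulated data. `chain` is the path over all
#' variables; `modular_blocks` partitions variables into equally sized
#' blocks that are complete within themselves, with one bridge edge between
#' consecutive blocks (a module-plus-hub architecture); `random_sparse`
#' draws Erdos-Renyi edges at the configured density.
#'
#' @param config a [simulation_config()].
#' @return a `truth_graph`: list with `variables` (a [variable_spec()]
#'   table; binary variables last), `edges` (data.frame `var1`, `var2`,
#'   `rho`) and `blocks` (named block labels for `modular_blocks`, else
#'   `NULL`).
#' @export
make_truth_graph <- function(config) {
  p <- config$n_continuous + config$n_binary
  if (p < 2) stop("need at least 2 variables")
  nms <- sprintf("v%03d", seq_len(p))
  kinds <- c(rep("continuous", config$n_continuous),
             rep("binary", config$n_binary))
  vars <- variable_spec(nms, kinds,
                        layer = ifelse(kinds == "continuous",
                                       "metabolomics", "phenotype"))
  blocks <- NULL
  if (config$structure == "chain") {
    e <- data.frame(var1 = nms[-p], var2 = nms[-1], stringsAsFactors = FALSE)
  } else if (config$structure == "modular_blocks") {
    if (p %% config$n_blocks != 0)
      stop("n_blocks = ", config$n_blocks, " must divide p = ", p)
    size <- p %/% config$n_blocks
    if (size < 2) stop("blocks need at least 2 variables")
    blocks <- setNames(rep(seq_len(config$n_blocks), each = size), nms)
    e <- do.call(rbind, lapply(seq_len(config$n_blocks), function(bl) {
      members <- nms[blocks == bl]
      cmb <- t(combn(members, 2))
      data.frame(var1 = cmb[, 1], var2 = cmb[, 2], stringsAsFactors = FALSE)
    }))
    # one bridge between consecutive blocks: last member -> first member
    if (config$n_blocks > 1) {
      bridge <- data.frame(
        var1 = nms[seq_len(config$n_blocks - 1) * size],
        var2 = nms[seq_len(config$n_blocks - 1) * size + 1],
        stringsAsFactors = FALSE)
      e <- rbind(e, bridge)
    }
  } else {
    set.seed(derive_seed(config$seed, "truth"))
    cmb <- t(combn(nms, 2))
    keep <- runif(nrow(cmb)) < config$density
    e <- data.frame(var1 = cmb[keep, 1], var2 = cmb[keep, 2],
                    stringsAsFactors = FALSE)
  }
  e$rho <- rep(config$rho, nrow(e))
  structure(list(variables = vars, edges = e, blocks = blocks),
            class = "truth_graph")
}

truth_edge_keys <- function(truth) pair_key(truth$edges$var1,
                                            truth$edges$var2)

#' Precision matrix implied by a truth graph
#'
#' Starts from the identity with `-rho` on every edge, symmetrizes, and
#' adds diagonal loading until the smallest eigenvalue reaches 0.05; the
#' implied covariance is then rescaled to unit diagonal (a correlation
#' matrix), which leaves partial correlations untouched. Off the edge set
#' the partial correlations are exactly zero; on it they keep the sign of
#' `rho` with magnitude shrunk by the loading (guaranteed within 50% of
#' `|rho|`).
#'
#' @param truth a `truth_graph`.
#' @return list with `precision`, `covariance` (correlation-scaled) and
#'   `partial` (the realized partial-correlation matrix).
#' @export
precision_from_graph <- function(truth) {
  nms <- truth$variables$name
  p <- length(nms)
  Omega <- diag(p)
  dimnames(Omega) <- list(nms, nms)
  for (e in seq_len(nrow(truth$edges))) {
    i <- truth$edges$var1[e]; j <- truth$edges$var2[e]
    Omega[i, j] <- Omega[j, i] <- -truth$edges$rho[e]
  }
  target_min <- 0.05
  delta <- 0
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < target_min) delta <- target_min - min(ev)
  if (1 + delta > 2)  # loading shrinks partials by 1/(1 + delta)
    stop("cannot reach positive definiteness without shrinking partial ",
         "correlations by more than 50%; lower rho or the graph density")
  diag(Omega) <- 1 + delta
  Sigma <- solve(Omega)
  d <- sqrt(diag(Sigma))
  Sigma <- Sigma / outer(d, d)           # correlation scale
  Omega_c <- solve(Sigma)
  pc <- -Omega_c / sqrt(outer(diag(Omega_c), diag(Omega_c)))
  diag(pc) <- 1
  list(precision = Omega_c, covariance = Sigma, partial = pc)
}

#' Simulate a mixed-type dataset from a truth graph
#'
#' Draws latent multivariate-normal samples with the covariance implied by
#' [precision_from_graph()]. Continuous variables are the latent values
#' plus a per-(family, variable) random intercept of variance 0.2 shared by
#' family members (the twin-relatedness signal the family meta-variable is
#' meant to absorb); binary variables are indicators `latent > 0`. Cells
#' are then masked missing completely at random at the configured rate.
#'
#' @param truth a `truth_graph`.
#' @param config the matching [simulation_config()].
#' @return a [mixed_dataset()] with family ids (`fam001`, ...).
#' @export
simulate_mixed <- function(truth, config) {
  prec <- precision_from_graph(truth)
  nms <- truth$variables$name
  p <- length(nms)
  n <- config$n_samples
  set.seed(derive_seed(config$seed, "latent"))
  Z <- matrix(rnorm(n * p), n, p)
  L <- chol(prec$covariance)
  latent <- Z %*% L
  colnames(latent) <- nms
  # family structure: pairs first, then singletons
  n_pairs <- config$n_samples - config$n_families
  fam_ids <- sprintf("fam%03d", c(rep(seq_len(n_pairs), each = 2),
                                  seq_len(config$n_families -
                                            n_pairs) + n_pairs))
  set.seed(derive_seed(config$seed, "family"))
  cont <- which(truth$variables$kind == "continuous")
  intercepts <- matrix(rnorm(config$n_families * length(cont),
                             sd = sqrt(0.2)),
                       config$n_families, length(cont))
  fam_index <- as.integer(sub("fam", "", fam_ids))
  values <- as.data.frame(latent, stringsAsFactors = FALSE)
  for (ci in seq_along(cont))
    values[[cont[ci]]] <- latent[, cont[ci]] + intercepts[fam_index, ci]
  for (j in which(truth$variables$kind == "binary"))
    values[[j]] <- as.numeric(latent[, j] > 0)
  if (config$missing_rate > 0) {
    set.seed(derive_seed(config$seed, "missing"))
    mask <- matrix(runif(n * p) < config$missing_rate, n, p)
    for (j in seq_len(p)) values[mask[, j], j] <- NA
  }
  mixed_dataset(values, truth$variables, family_ids = fam_ids)
}

#' Edge-recovery metrics
#'
#' Precision, recall and F1 of an inferred edge set against the truth
#' graph, computed on unordered pairs. F1 is 0 when either set is empty
#' while the other is not, and 1 when both are empty.
#'
#' @param inferred character vector of pair keys, or an `igraph`.
#' @param truth a `truth_graph`.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
recovery_metrics <- function(inferred, truth) {
  if (inherits(inferred, "igraph")) inferred <- graph_edge_keys(inferred)
  truth_keys <- truth_edge_keys(truth)
  tp <- length(intersect(inferred, truth_keys))
  prec <- if (length(inferred)) tp / length(inferred) else
    as.numeric(length(truth_keys) == 0)
  rec <- if (length(truth_keys)) tp / length(truth_keys) else
    as.numeric(length(inferred) == 0)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  if (!length(inferred) && !length(truth_keys)) f1 <- 1
  c(precision = prec, recall = rec, f1 = f1)
}
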