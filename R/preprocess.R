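#' Drop samples and variables with excessive missingness
#'
#' Two fixed passes: first samples whose fraction of missing cells is
#' strictly above `sample_max_missing` are removed, then variables whose
#' missing fraction — computed on the remaining samples — is strictly above
#' `variable_max_missing`. The strict inequality means a variable missing in
#' exactly 20% of samples is retained at the default thresholds.
#'
#' @param dataset a [mixed_dataset()].
#' @param sample_max_missing,variable_max_missing maximal tolerated missing
#'   fractions in \[0, 1\] (defaults 0.2).
#' @return a list with elements `dataset` (filtered) and `report` (a
#'   `preprocess_report` recording dropped ids and remaining missing cells).
#' @export
filter_missing <- function(dataset, sample_max_missing = 0.2,
                           variable_max_missing = 0.2) {
  stopifnot(sample_max_missing >= 0, sample_max_missing <= 1,
            variable_max_missing >= 0, variable_max_missing <= 1)
  obs <- dataset$observed
  samp_miss <- 1 - rowMeans(obs)
  keep_s <- samp_miss <= sample_max_missing
  if (!any(keep_s))
    stop("all samples exceed the missingness threshold; empty dataset")
  var_miss <- 1 - colMeans(obs[keep_s, , drop = FALSE])
  keep_v <- var_miss <= variable_max_missing
  out <- subset_dataset(dataset, samples = which(keep_s),
                        variables = dataset$variables$name[keep_v])
  report <- structure(list(
    dropped_samples = dataset$sample_ids[!keep_s],
    dropped_variables = dataset$variables$name[!keep_v],
    n_imputed_cells = sum(!out$observed),
    transform_log = character(0)), class = "preprocess_report")
  list(dataset = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report> dropped ", length(x$dropped_samples),
      " samples, ", length(x$dropped_variables), " variables; ",
      x$n_imputed_cells, " cells to impute\n", sep = "")
  invisible(x)
}

.mode_value <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  # deterministic tie-break: most frequent, then smallest label
  best <- names(tab)[tab == tab[1]]
  sort(best)[1]
}

#' Impute remaining missing values
#'
#' `median_mode` replaces missing continuous values by the per-variable
#' median of observed values and missing binary/categorical values by the
#' observed mode (ties broken towards the smaller label). `knn` finds for
#' each incomplete sample its `k` nearest neighbours under a mean
#' per-variable distance over commonly observed cells (absolute difference
#' scaled by the variable's observed standard deviation for continuous,
#' 0/1 mismatch otherwise) and imputes the neighbours' mean (continuous) or
#' mode. Both methods are deterministic; `seed` is kept in the signature for
#' interface stability.
#'
#' @param dataset a [mixed_dataset()].
#' @param method `"median_mode"` (default) or `"knn"`.
#' @param k neighbours for `knn` (default 5).
#' @param seed integer, unused by the deterministic methods.
#' @return a fully observed [mixed_dataset()].
#' @export
impute_missing <- function(dataset, method = c("median_mode", "knn"), k = 5,
                           seed = 1L) {
  method <- match.arg(method)
  obs <- dataset$observed
  empty <- colSums(obs) == 0
  if (any(empty))
    stop("variable(s) with zero observed values: ",
         paste(dataset$variables$name[empty], collapse = ", "))
  values <- dataset$values
  vars <- dataset$variables
  if (method == "median_mode") {
    for (j in seq_len(ncol(values))) {
      miss <- !obs[, j]
      if (!any(miss)) next
      col <- values[[j]]
      fill <- if (vars$kind[j] == "continuous") median(col[obs[, j]])
              else if (vars$kind[j] == "binary")
                as.numeric(.mode_value(col[obs[, j]]))
              else .mode_value(col[obs[, j]])
      col[miss] <- fill
      values[[j]] <- col
    }
  } else {
    # pairwise distances on commonly observed cells
    n <- nrow(values)
    num <- matrix(NA_real_, n, ncol(values))
    for (j in seq_len(ncol(values))) {
      if (vars$kind[j] == "categorical") {
        num[, j] <- as.numeric(factor(values[[j]], levels = vars$levels[[j]]))
      } else num[, j] <- values[[j]]
    }
    scale_j <- vapply(seq_len(ncol(values)), function(j) {
      if (vars$kind[j] == "continuous") {
        s <- sd(num[obs[, j], j]); if (is.na(s) || s == 0) 1 else s
      } else 1
    }, 0)
    dist_ij <- function(i, l) {
      common <- obs[i, ] & obs[l, ]
      if (!any(common)) return(Inf)
      d <- numeric(0)
      for (j in which(common)) {
        d <- c(d, if (vars$kind[j] == "continuous")
          abs(num[i, j] - num[l, j]) / scale_j[j]
          else as.numeric(num[i, j] != num[l, j]))
      }
      mean(d)
    }
    incomplete <- which(rowSums(!obs) > 0)
    for (i in incomplete) {
      dists <- vapply(seq_len(n), function(l) if (l == i) Inf else dist_ij(i, l), 0)
      for (j in which(!obs[i, ])) {
        cand <- which(obs[, j] & is.finite(dists))
        if (!length(cand)) stop("no neighbour observes variable '",
                                vars$name[j], "' for sample ", i)
        ord <- cand[order(dists[cand], cand)]
        nb <- ord[seq_len(min(k, length(ord)))]
        values[i, j] <- if (vars$kind[j] == "continuous")
          mean(values[nb, j]) else
            if (vars$kind[j] == "binary")
              as.numeric(.mode_value(values[nb, j])) else
                .mode_value(values[nb, j])
      }
    }
  }
  mixed_dataset(values, vars, sample_ids = dataset$sample_ids,
                family_ids = dataset$family_ids)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles of their offset ranks,
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default. Ties receive average ranks, so tied inputs map to equal outputs;
#' rank order is preserved and tie-free input maps symmetrically about 0.
#'
#' @param values numeric vector without missing values, length >= 2, not
#'   constant.
#' @param offset rank offset `c` (default 3/8; `0.5` gives the van der
#'   Waerden-type variant).
#' @return numeric vector of the same length.
#' @export
inverse_normal <- function(values, offset = 3/8) {
  if (anyNA(values)) stop("inverse_normal requires complete values")
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (max(values) == min(values))
    stop("constant vector: ranks are degenerate")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Apply the inverse-normal transform to all continuous variables
#'
#' Convenience wrapper used by the pipeline: every continuous variable of a
#' complete dataset is replaced by its inverse-normal transform.
#'
#' @param dataset a complete [mixed_dataset()].
#' @param offset passed to [inverse_normal()].
#' @return the transformed dataset.
#' @export
inverse_normal_dataset <- function(dataset, offset = 3/8) {
  if (!all(dataset$observed)) stop("impute before transforming")
  values <- dataset$values
  for (j in which(dataset$variables$kind == "continuous"))
    values[[j]] <- inverse_normal(values[[j]], offset = offset)
  mixed_dataset(values, dataset$variables, sample_ids = dataset$sample_ids,
                family_ids = dataset$family_ids)
}

#' Recode categorical variables as binary indicators
#'
#' Each categorical variable with `L` levels (excluding the `meta` layer) is
#' replaced by `L - 1` binary indicator variables named `"<var>::<level>"`,
#' the first metadata level acting as reference. Binary and continuous
#' variables pass through unchanged; missing cells stay missing in every
#' indicator.
#'
#' @param dataset a [mixed_dataset()].
#' @return the recoded dataset.
#' @export
dichotomize <- function(dataset) {
  vars <- dataset$variables
  new_cols <- list()
  new_name <- new_kind <- new_layer <- character(0)
  new_levels <- list()
  for (j in seq_len(nrow(vars))) {
    if (vars$kind[j] != "categorical" || vars$layer[j] == "meta") {
      new_cols[[length(new_cols) + 1]] <- dataset$values[[j]]
      new_name <- c(new_name, vars$name[j])
      new_kind <- c(new_kind, vars$kind[j])
      new_layer <- c(new_layer, vars$layer[j])
      new_levels <- c(new_levels, list(vars$levels[[j]] %||% character(0)))
      next
    }
    lev <- vars$levels[[j]]
    if (length(lev) < 2)
      stop("categorical variable '", vars$name[j],
           "' has a single level; cannot dichotomize")
    col <- dataset$values[[j]]
    for (l in lev[-1]) {
      ind <- as.numeric(col == l)
      new_cols[[length(new_cols) + 1]] <- ind
      new_name <- c(new_name, paste0(vars$name[j], "::", l))
      new_kind <- c(new_kind, "binary")
      new_layer <- c(new_layer, vars$layer[j])
      new_levels <- c(new_levels, list(character(0)))
    }
  }
  values <- as.data.frame(new_cols, stringsAsFactors = FALSE)
  names(values) <- new_name
  mixed_dataset(values, variable_spec(new_name, new_kind, new_layer,
                                      new_levels),
                sample_ids = dataset$sample_ids,
                family_ids = dataset$family_ids)
}

#' Attach the family indicator variable
#'
#' Adds one categorical variable (layer `meta`, name `"family"`) whose value
#' for each sample is its family id. Including it in the inference lets the
#' forests absorb family-shared variation (twin relatedness);
#' [infer_mgm()] removes the corresponding node from the returned network.
#'
#' @param dataset a [mixed_dataset()] with family ids.
#' @return the dataset with the appended meta variable.
#' @export
attach_family_variable <- function(dataset) {
  if (any(dataset$variables$layer == "meta"))
    stop("a meta-layer variable is already present; ",
         "attach_family_variable applied twice?")
  lev <- unique(dataset$family_ids)
  values <- dataset$values
  values[["family"]] <- dataset$family_ids
  vars <- rbind(dataset$variables[, c("name", "kind", "layer")],
                data.frame(name = "family", kind = "categorical",
                           layer = "meta", stringsAsFactors = FALSE))
  levels <- c(dataset$variables$levels, list(lev))
  mixed_dataset(values, variable_spec(vars$name, vars$kind, vars$layer,
                                      levels),
                sample_ids = dataset$sample_ids,
                family_ids = dataset$family_ids)
}
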