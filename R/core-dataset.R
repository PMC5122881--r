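#' Variable metadata table
#'
#' Builds the per-variable metadata used throughout the package. Each
#' variable has a unique name, a kind (`continuous`, `binary`,
#' `categorical`) and an omics layer (`epigenomics`, `transcriptomics`,
#' `glycomics`, `metabolomics`, `dxa`, `phenotype`, `meta`). Categorical
#' variables additionally carry their ordered level labels; the first level
#' is the reference used by [dichotomize()].
#'
#' @param name character vector of unique variable names.
#' @param kind character vector, one of `"continuous"`, `"binary"`,
#'   `"categorical"` per variable.
#' @param layer character vector of omics layers (default `"phenotype"`).
#' @param levels list of character vectors of category labels; required
#'   (non-empty) exactly for categorical variables.
#' @return a `data.frame` with columns `name`, `kind`, `layer` and a
#'   list-column `levels`.
#' @export
variable_spec <- function(name, kind, layer = "phenotype", levels = NULL) {
  kinds <- c("continuous", "binary", "categorical")
  layers <- c("epigenomics", "transcriptomics", "glycomics", "metabolomics",
              "dxa", "phenotype", "meta")
  name <- as.character(name)
  p <- length(name)
  kind <- rep_len(as.character(kind), p)
  layer <- rep_len(as.character(layer), p)
  if (anyDuplicated(name))
    stop("variable names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (!all(kind %in% kinds))
    stop("unknown variable kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  if (!all(layer %in% layers))
    stop("unknown layer: ", paste(setdiff(layer, layers), collapse = ", "))
  if (is.null(levels)) levels <- vector("list", p)
  if (length(levels) != p) stop("`levels` must have one entry per variable")
  for (i in seq_len(p)) {
    if (kind[i] == "categorical" && length(levels[[i]]) == 0)
      stop("categorical variable '", name[i], "' needs non-empty levels")
    if (kind[i] != "categorical" && length(levels[[i]]) > 0)
      stop("non-categorical variable '", name[i], "' must not declare levels")
  }
  out <- data.frame(name = name, kind = kind, layer = layer,
                    stringsAsFactors = FALSE)
  out$levels <- levels
  out
}

#' Mixed-type dataset container
#'
#' A samples-by-variables table of mixed continuous/binary/categorical
#' values together with an observedness mask, per-variable metadata and a
#' family id per sample (twin-pair structure). Continuous and binary
#' variables are stored as numeric columns, categorical variables as
#' character columns.
#'
#' @param values a `data.frame` (samples x variables) of values; `NA` marks
#'   missing cells.
#' @param variables metadata as built by [variable_spec()]; order must match
#'   the columns of `values`.
#' @param sample_ids character vector of unique sample ids (default
#'   `"s1"..."sn"`).
#' @param family_ids character vector of family ids, one per sample; twins
#'   share an id. Default: every sample its own family.
#' @return an object of class `mixed_dataset` with elements `values`,
#'   `observed` (logical matrix), `variables`, `sample_ids`, `family_ids`.
#' @export
mixed_dataset <- function(values, variables, sample_ids = NULL,
                          family_ids = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (is.null(family_ids)) family_ids <- sample_ids
  family_ids <- as.character(family_ids)
  if (ncol(values) != nrow(variables))
    stop("values has ", ncol(values), " columns but metadata describes ",
         nrow(variables), " variables")
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the number of rows")
  if (length(family_ids) != n)
    stop("family_ids must have one entry per sample")
  if (any(!nzchar(family_ids)) || anyNA(family_ids))
    stop("family_ids must be non-empty strings")
  colnames(values) <- variables$name
  rownames(values) <- NULL
  # coerce column types by kind and validate observed values
  for (j in seq_len(ncol(values))) {
    kind <- variables$kind[j]
    nm <- variables$name[j]
    if (kind %in% c("continuous", "binary")) {
      col <- values[[j]]
      if (is.character(col)) {
        col[col %in% c("", "NA")] <- NA
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & is.na(num))
        if (length(bad))
          stop("non-numeric value for ", kind, " variable '", nm,
               "' in row ", bad[1])
        col <- num
      }
      col <- as.numeric(col)
      if (kind == "continuous" && any(!is.finite(col) & !is.na(col)))
        stop("non-finite observed value in continuous variable '", nm, "'")
      if (kind == "binary" && !all(col[!is.na(col)] %in% c(0, 1)))
        stop("binary variable '", nm, "' has observed values outside {0,1}")
      values[[j]] <- col
    } else {
      col <- as.character(values[[j]])
      col[!is.na(col) & col %in% c("", "NA")] <- NA
      lev <- variables$levels[[j]]
      bad <- setdiff(unique(col[!is.na(col)]), lev)
      if (length(bad))
        stop("categorical variable '", nm, "' has values outside its levels: ",
             paste(bad, collapse = ", "))
      values[[j]] <- col
    }
  }
  observed <- !is.na(as.matrix(values))
  dimnames(observed) <- list(NULL, variables$name)
  structure(list(values = values, observed = observed, variables = variables,
                 sample_ids = sample_ids, family_ids = family_ids),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat("<mixed_dataset> ", length(x$sample_ids), " samples x ",
      nrow(x$variables), " variables\n", sep = "")
  cat("  kinds: ", paste(sprintf("%s=%d", names(table(x$variables$kind)),
                                 table(x$variables$kind)), collapse = ", "),
      "\n", sep = "")
  miss <- 1 - mean(x$observed)
  cat(sprintf("  missing cells: %.1f%%; families: %d\n", 100 * miss,
              length(unique(x$family_ids))))
  invisible(x)
}

n_samples <- function(dataset) length(dataset$sample_ids)
n_variables <- function(dataset) nrow(dataset$variables)

# Subset a mixed_dataset by sample index/id and/or variable names.
subset_dataset <- function(dataset, samples = NULL, variables = NULL) {
  si <- seq_along(dataset$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, dataset$sample_ids)
          else samples
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  vi <- seq_len(nrow(dataset$variables))
  if (!is.null(variables)) {
    vi <- match(variables, dataset$variables$name)
    if (anyNA(vi)) stop("unknown variable in subset")
  }
  vars <- dataset$variables[vi, , drop = FALSE]
  rownames(vars) <- NULL
  mixed_dataset(dataset$values[si, vi, drop = FALSE], vars,
                sample_ids = dataset$sample_ids[si],
                family_ids = dataset$family_ids[si])
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
           na.strings = c("", "NA"), colClasses = "character")
}

#' Load a mixed dataset from tabular files
#'
#' Reads a samples-by-variables data table and a variable-metadata table.
#' Comma or tab separation is auto-detected from the file extension; empty
#' cells and `"NA"` are treated as missing. The metadata table must have
#' columns `name`, `kind`, `layer`, and optionally `levels`
#' (semicolon-separated category labels for categorical variables; when
#' absent, levels are taken from the observed values in sorted order). A
#' `sample_id` column in the data file supplies sample ids and a column
#' named by `family_column` supplies family ids; both are optional.
#'
#' @param data_file path to the CSV/TSV data table (header = variable names,
#'   one row per sample).
#' @param metadata_file path to the CSV/TSV variable metadata table.
#' @param family_column name of the data column holding family ids
#'   (default `"family_id"`).
#' @return a [mixed_dataset()].
#' @export
load_dataset <- function(data_file, metadata_file, family_column = "family_id") {
  raw <- .read_table_auto(data_file)
  meta <- .read_table_auto(metadata_file)
  if (!all(c("name", "kind", "layer") %in% names(meta)))
    stop("metadata file must have columns name, kind, layer")
  sample_ids <- NULL
  if ("sample_id" %in% names(raw)) {
    sample_ids <- raw[["sample_id"]]
    raw[["sample_id"]] <- NULL
  }
  family_ids <- NULL
  if (family_column %in% names(raw)) {
    family_ids <- raw[[family_column]]
    raw[[family_column]] <- NULL
  }
  only_data <- setdiff(names(raw), meta$name)
  only_meta <- setdiff(meta$name, names(raw))
  if (length(only_data) || length(only_meta))
    stop("variable name mismatch between data and metadata; data-only: {",
         paste(only_data, collapse = ", "), "}; metadata-only: {",
         paste(only_meta, collapse = ", "), "}")
  meta <- meta[match(names(raw), meta$name), , drop = FALSE]  # data order wins
  levels <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (meta$kind[i] == "categorical") {
      levels[[i]] <-
        if ("levels" %in% names(meta) && !is.na(meta$levels[i]) &&
            nzchar(meta$levels[i]))
          strsplit(meta$levels[i], ";", fixed = TRUE)[[1]]
        else sort(unique(raw[[meta$name[i]]][!is.na(raw[[meta$name[i]]])]))
    }
  }
  vars <- variable_spec(meta$name, meta$kind, meta$layer, levels)
  mixed_dataset(raw, vars, sample_ids = sample_ids, family_ids = family_ids)
}

#' Write a mixed dataset to tabular files
#'
#' Inverse of [load_dataset()]: writes the data table (with `sample_id` and
#' `family_id` columns) and the metadata table so that loading them back
#' reproduces values, mask, kinds, layers and levels exactly.
#'
#' @param dataset a [mixed_dataset()].
#' @param data_file,metadata_file output paths; `.tsv` extension selects tab
#'   separation, anything else comma.
#' @return invisibly, the dataset.
#' @export
write_dataset <- function(dataset, data_file, metadata_file) {
  out <- dataset$values
  fmt <- function(col) {
    if (is.numeric(col)) {
      s <- vapply(col, function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15), "")
      s
    } else as.character(col)
  }
  out <- as.data.frame(lapply(out, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  out <- cbind(sample_id = dataset$sample_ids,
               family_id = dataset$family_ids, out)
  meta <- dataset$variables
  meta$levels <- vapply(meta$levels, paste, "", collapse = ";")
  sep_of <- function(p) if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
  write.table(out, data_file, sep = sep_of(data_file), row.names = FALSE,
              quote = FALSE, na = "")
  write.table(meta, metadata_file, sep = sep_of(metadata_file),
              row.names = FALSE, quote = FALSE, na = "")
  invisible(dataset)
}
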