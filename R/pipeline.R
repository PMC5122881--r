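#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> inference -> topology -> modules ->
#' robustness from one flat configuration and writes every artifact plus a
#' manifest of the parameters and stage seeds, so that re-running with the
#' same configuration reproduces all outputs byte-for-byte.
#'
#' @param config either a path to a YAML file or a named list. Recognized
#'   keys (defaults in parentheses): `data`, `meta` — input tables, or
#'   `dataset` (a [mixed_dataset()]) passed programmatically;
#'   `out_dir` (`"grafonet_run"`); `sample_missing` (0.2),
#'   `variable_missing` (0.2), `impute` (`"median_mode"`), `blom_offset`
#'   (0.375); `B` (100), `q` (`NULL` = automatic), `tau` (0.8), `trees`
#'   (500), `importance` (`"permutation"`); `module_method` (`"greedy"`),
#'   `cutoffs` (0.2,0.4,0.6,0.8,1.0), `background_draws` (1000);
#'   `seed` (1).
#' @return invisibly, a list with the in-memory results (`dataset`,
#'   `graph`, `stability`, `topology`, `partition`, `robustness`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(key, default) config[[key]] %||% default
  out_dir <- cfg("out_dir", "grafonet_run")
  seed <- as.integer(cfg("seed", 1L))
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # -- load ----------------------------------------------------------------
  if (!is.null(config$dataset)) {
    dataset <- config$dataset
  } else {
    for (key in c("data", "meta"))
      if (is.null(config[[key]]) || !file.exists(config[[key]]))
        stop("input path missing or not found: ", key, " = ",
             config[[key]] %||% "<unset>")
    dataset <- load_dataset(config$data, config$meta,
                            family_column = cfg("family_column", "family_id"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log("loaded %d samples x %d variables", n_samples(dataset),
      n_variables(dataset))

  # -- preprocess ----------------------------------------------------------
  filt <- filter_missing(dataset, cfg("sample_missing", 0.2),
                         cfg("variable_missing", 0.2))
  log("missingness filter: dropped %d samples, %d variables",
      length(filt$report$dropped_samples),
      length(filt$report$dropped_variables))
  clean <- impute_missing(filt$dataset, method = cfg("impute", "median_mode"),
                          seed = derive_seed(seed, "impute"))
  clean <- inverse_normal_dataset(clean, offset = cfg("blom_offset", 0.375))
  clean <- dichotomize(clean)
  families_informative <- any(table(clean$family_ids) > 1)
  if (families_informative) clean <- attach_family_variable(clean)
  log("preprocessed: %d variables after indicator coding%s",
      n_variables(clean),
      if (families_informative) " (+ family meta-variable)" else "")
  write_dataset(clean, file.path(out_dir, "clean.csv"),
                file.path(out_dir, "clean_meta.csv"))

  # -- inference -----------------------------------------------------------
  inf_cfg <- inference_config(
    B = cfg("B", 100L), q = config$q, tau = cfg("tau", 0.8),
    rf_trees = cfg("trees", 500L),
    rf_importance = cfg("importance", "permutation"),
    seed = derive_seed(seed, "inference"))
  fit <- infer_mgm(clean, inf_cfg)
  log("inferred model: %d nodes, %d edges (q = %d, tau = %.2f, B = %d)",
      igraph::vcount(fit$graph), igraph::ecount(fit$graph), fit$q,
      inf_cfg$tau, inf_cfg$B)
  write_mgm_graphml(fit$graph, file.path(out_dir, "model.graphml"))
  write.table(fit$stability, file.path(out_dir, "stability.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # -- topology + modules --------------------------------------------------
  topo <- node_centralities(fit$graph)
  write.table(topo$nodes, file.path(out_dir, "topology.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  part <- detect_modules(fit$graph, method = cfg("module_method", "greedy"),
                         seed = derive_seed(seed, "modules"))
  write.table(data.frame(node = names(part$membership),
                         module = as.integer(part$membership)),
              file.path(out_dir, "partition.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log("topology: mean degree %.2f, mean clustering %.3f; %d modules (Q = %.3f)",
      topo$mean_degree, topo$mean_clustering,
      length(unique(part$membership)), part$modularity)

  # -- robustness ----------------------------------------------------------
  rob <- stability_report(fit$stability, fit$graph,
                          cutoffs = cfg("cutoffs", c(0.2, 0.4, 0.6, 0.8, 1)),
                          n_draws = cfg("background_draws", 1000L),
                          method = cfg("module_method", "greedy"),
                          seed = derive_seed(seed, "robustness"))
  jsonlite::write_json(
    list(per_cutoff = rob$per_cutoff,
         background_ari_mean = mean(rob$background_ari),
         background_ari_q95 = unname(
           stats::quantile(rob$background_ari, 0.95))),
    file.path(out_dir, "robustness.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = seed,
    stage_seeds = list(impute = derive_seed(seed, "impute"),
                       inference = derive_seed(seed, "inference"),
                       modules = derive_seed(seed, "modules"),
                       robustness = derive_seed(seed, "robustness")),
    preprocess = list(sample_missing = cfg("sample_missing", 0.2),
                      variable_missing = cfg("variable_missing", 0.2),
                      impute = cfg("impute", "median_mode"),
                      blom_offset = cfg("blom_offset", 0.375)),
    inference = list(B = inf_cfg$B, q = fit$q, tau = inf_cfg$tau,
                     trees = inf_cfg$rf_trees,
                     importance = inf_cfg$rf_importance),
    analysis = list(module_method = cfg("module_method", "greedy"),
                    cutoffs = cfg("cutoffs", c(0.2, 0.4, 0.6, 0.8, 1)),
                    background_draws = cfg("background_draws", 1000L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(dataset = clean, graph = fit$graph,
                 stability = fit$stability, q = fit$q, topology = topo,
                 partition = part, robustness = rob, manifest = manifest))
}
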