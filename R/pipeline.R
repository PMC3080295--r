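# End-to-end orchestration: inputs (read or simulated) -> data-driven query
# selection -> ontology model -> integrated kNN retrieval -> biosignature
# model family -> LOOCV comparison, k sweep and overlap statistics, with a
# manifest and content-addressed stage caching for reproducible re-runs.

.md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f)
  unname(tools::md5sum(f))
}

# Content-addressed stage cache: recomputing an unchanged stage reuses the
# stored result.
.stage <- function(cache_dir, name, key, fun) {
  if (is.null(cache_dir)) return(fun())
  path <- file.path(cache_dir, paste0(name, "-", .md5_of(key), ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- fun()
  saveRDS(value, path)
  value
}

.default_pipeline_config <- function() {
  list(namespace = "BP", aggregation = "max_pair", k = 15,
       k_range = c(1L, 20L), representation = "integrated_neighborhood",
       cost = 100, fold_change = 1.7, fdr = 0.01, n_perm = 1000,
       n_de_queries = 4, seed = 1, cache = TRUE)
}

#' Run the full biosignature discovery pipeline
#'
#' Orchestrates every stage of the package on either simulated or on-disk
#' inputs: (1) load or simulate the expression cohort, ontology,
#' annotations and optional interaction network; (2) select data-driven
#' queries by the SAM-style fold-change/FDR rule; (3) build the
#' per-namespace ontology model; (4) fit integrated kNN neighbourhoods for
#' the expert and data-driven query sets; (5) assemble and compare the
#' biosignature model family (queries alone, queries + kNN neighbourhoods,
#' queries + interaction partners) under LOOCV; (6) sweep the neighbourhood
#' size k; (7) compute kNN-vs-interaction neighbourhood overlap statistics;
#' and (8) export neighbourhood networks, result tables, a JSON report and
#' a manifest recording the configuration hash, input hashes and package
#' version. Unchanged stages are served from a content-addressed cache
#' under `out_dir/cache`.
#'
#' @param config A named list or the path to a JSON file. Recognised
#'   fields: either `simulate` (arguments for [sim_config()]) or input
#'   paths `expression`, `labels`, `obo`, `gaf`, optional `edges` and
#'   `queries` (plain-text file, one query gene per line); plus the
#'   tunables `namespace` (`"BP"`), `aggregation`, `k` (15), `k_range`
#'   (`c(1, 20)`), `representation`, `cost` (100), `fold_change` (1.7),
#'   `fdr` (0.01), `n_perm` (1000), `n_de_queries` (4), `seed` (1) and
#'   `cache` (TRUE).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted objects (`fit`, `comparison`,
#'   `auc_curve`, `overlap`, `de`) and the paths written.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- if (isTRUE(cfg$cache)) file.path(out_dir, "cache") else NULL
  if (!is.null(cache_dir)) dir.create(cache_dir, showWarnings = FALSE)

  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  ## stage: inputs -----------------------------------------------------
  inputs <- tryCatch({
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(sim_config, utils::modifyList(
        list(seed = cfg$seed), as.list(cfg$simulate)))
      .stage(cache_dir, "inputs", sim_cfg, function() {
        ds <- simulate_dataset(sim_cfg)
        ds$queries <- ds$config$queries
        ds
      })
    } else {
      needed <- c("expression", "labels", "obo", "gaf")
      miss <- needed[!vapply(needed, function(f) !is.null(cfg[[f]]), TRUE)]
      if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
      key <- unname(tools::md5sum(unlist(cfg[c(needed, "edges", "queries")],
                                         use.names = FALSE)))
      .stage(cache_dir, "inputs", key, function() {
        list(expr = read_expression(cfg$expression, labels = cfg$labels),
             graph = read_obo(cfg$obo),
             annotations = read_gaf(cfg$gaf),
             network = if (!is.null(cfg$edges)) read_edges(cfg$edges),
             queries = if (!is.null(cfg$queries))
               readLines(cfg$queries, warn = FALSE))
      })
    }
  }, error = function(e) fail("inputs", e))

  ## stage: data-driven queries ---------------------------------------
  de <- tryCatch(
    .stage(cache_dir, "diffexpr",
           list(dim(inputs$expr), cfg$n_perm, cfg$seed),
           function() sam_de(inputs$expr, n_perm = cfg$n_perm,
                             seed = cfg$seed)),
    error = function(e) fail("diffexpr", e))
  de_queries <- utils::head(
    suppressWarnings(select_queries(de, cfg$fold_change, cfg$fdr)),
    cfg$n_de_queries)

  ## stage: ontology model ---------------------------------------------
  model <- tryCatch(
    .stage(cache_dir, "ontology_model",
           list(inputs$graph, nrow(inputs$annotations), cfg$namespace),
           function() build_ontology_model(inputs$graph, inputs$annotations,
                                           cfg$namespace)),
    error = function(e) fail("ontology_model", e))

  ## stage: integrated kNN ---------------------------------------------
  queries <- inputs$queries
  if (is.null(queries)) queries <- de_queries
  if (!length(queries)) fail("knn", simpleError("no query genes available"))
  fit <- tryCatch(
    .stage(cache_dir, "knn",
           list(queries, cfg$k, cfg$aggregation, cfg$namespace, dim(inputs$expr)),
           function() iknn(inputs$expr, model, queries, k = cfg$k,
                           aggregation = cfg$aggregation)),
    error = function(e) fail("knn", e))
  fit_de <- if (length(de_queries)) tryCatch(
    suppressWarnings(iknn(inputs$expr, model, de_queries,
                          k = min(cfg$k, 4), aggregation = cfg$aggregation)),
    error = function(e) NULL)

  ## stage: model family -----------------------------------------------
  sigs <- list(
    biosignature(queries, "individual_gene", name = "EDQ"),
    biosignature(fit, "integrated_neighborhood",
                 name = sprintf("EDQ+%dNN", fit$k))
  )
  if (!is.null(fit_de)) {
    sigs <- c(sigs, list(
      biosignature(de_queries, "individual_gene", name = "DE"),
      biosignature(fit_de, "integrated_neighborhood",
                   name = sprintf("DE+%dNN", fit_de$k))
    ))
  }
  ppi_sets <- NULL
  if (!is.null(inputs$network)) {
    ppi_sets <- stats::setNames(
      lapply(fit$queries, function(q) ppi_neighbors(inputs$network, q)),
      fit$queries)
    sigs <- c(sigs, list(
      biosignature(ppi_sets, "integrated_neighborhood", name = "EDQ+PPI")))
  }
  comparison <- tryCatch(
    suppressWarnings(compare_models(sigs, inputs$expr, cost = cfg$cost)),
    error = function(e) fail("classify", e))

  k_range <- seq(cfg$k_range[1], cfg$k_range[length(cfg$k_range)])
  curve <- tryCatch(
    auc_by_k(fit, inputs$expr, k = k_range, cost = cfg$cost),
    error = function(e) fail("ksweep", e))

  overlap <- if (!is.null(ppi_sets)) {
    tryCatch(suppressWarnings(neighborhood_overlap(fit, ppi_sets, k = k_range)),
             error = function(e) fail("overlap", e))
  }

  ## stage: exports ----------------------------------------------------
  paths <- c(
    neighborhoods = file.path(out_dir, "neighborhoods.tsv"),
    network_sif = file.path(out_dir, "iknn_network.sif"),
    network_graphml = file.path(out_dir, "iknn_network.graphml"),
    comparison = file.path(out_dir, "model_comparison.tsv"),
    auc_by_k = file.path(out_dir, "auc_by_k.tsv"),
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.table(as.data.frame(fit), paths[["neighborhoods"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(fit, paths[["network_sif"]], "sif")
  export_network(fit, paths[["network_graphml"]], "graphml")
  utils::write.table(as.data.frame(comparison), paths[["comparison"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(curve), paths[["auc_by_k"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(overlap)) {
    paths[["overlap"]] <- file.path(out_dir, "overlap.tsv")
    utils::write.table(overlap$summary, paths[["overlap"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    queries = fit$queries,
    de_queries = de_queries,
    models = as.data.frame(unclass(comparison)[c("name", "representation",
                                                 "n_features", "auc")]),
    auc_by_k = as.data.frame(curve),
    overlap = if (!is.null(overlap)) overlap$summary
  )
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    package = "iknn",
    version = as.character(utils::packageVersion("iknn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = .md5_of(cfg[setdiff(names(cfg), c("out_dir", "cache"))]),
    input_hashes = if (is.null(cfg$simulate)) {
      as.list(tools::md5sum(unlist(cfg[c("expression", "labels", "obo",
                                         "gaf", "edges", "queries")],
                                   use.names = TRUE)))
    } else {
      list(simulated_seed = cfg$seed)
    }
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(fit = fit, fit_de = fit_de, de = de, comparison = comparison,
                 auc_curve = curve, overlap = overlap, paths = paths))
}
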