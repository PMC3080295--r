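# Seeded generators for a small two-condition microarray-style cohort with
# planted co-expressed, functionally coherent, treatment-responsive gene
# modules, plus a matching toy ontology, annotation corpus and interaction
# network. Every other part of the package is testable against these
# without downloading anything.

#' Simulation configuration
#'
#' Describes a two-condition cohort with planted gene modules. Each module
#' is a query gene plus `module_size` member genes that (a) share a latent
#' expression factor giving expected pairwise correlation `rho`, (b) share
#' a deep (high-information-content) ontology term, and (c) shift by
#' `delta` standard-deviation units in treated samples. The default 6 vs 6
#' cohort mirrors a small two-colour microarray study; 500 genes keeps
#' simulations fast while leaving a realistic excess of unrelated genes.
#'
#' @param n_genes Total number of genes (ids `G0001`, `G0002`, ...).
#' @param n_treated,n_control Samples per condition (each >= 2).
#' @param n_modules Number of planted modules.
#' @param module_size Members per module (excluding the query).
#' @param rho Expected within-module pairwise correlation, in `[0, 1)`.
#' @param delta Treatment effect on module genes, in sd units.
#' @param annotation_depth Depth of the module terms in the toy ontology.
#' @param noise_sd Standard deviation of unrelated (noise) genes.
#' @param baseline Baseline log2 intensity added to all values.
#' @param seed Integer seed; all generators derive their randomness from
#'   it, leaving the global RNG untouched.
#' @param modules Optional explicit module list (each element a list with
#'   `query`, `members`, and optionally `rho`, `delta`), overriding
#'   `n_modules`/`module_size`. Member sets must be disjoint.
#' @return An object of class `sim_config`; `$queries` holds the module
#'   query genes.
#' @export
sim_config <- function(n_genes = 500, n_treated = 6, n_control = 6,
                       n_modules = 2, module_size = 15, rho = 0.7,
                       delta = 2, annotation_depth = 4, noise_sd = 1,
                       baseline = 8, seed = 1, modules = NULL) {
  stopifnot(n_treated >= 2, n_control >= 2, rho >= 0, rho < 1,
            delta >= 0, annotation_depth >= 1, noise_sd > 0, .is_count(n_genes))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(modules)) {
    stopifnot(.is_count(n_modules), .is_count(module_size))
    if (n_modules * (module_size + 1) > n_genes) {
      stop("modules do not fit into n_genes")
    }
    modules <- lapply(seq_len(n_modules), function(m) {
      block <- gene_ids[((m - 1) * (module_size + 1) + 1):(m * (module_size + 1))]
      list(query = block[1L], members = block[-1L], rho = rho, delta = delta)
    })
  } else {
    modules <- lapply(modules, function(m) {
      if (is.null(m$rho)) m$rho <- rho
      if (is.null(m$delta)) m$delta <- delta
      stopifnot(m$rho >= 0, m$rho < 1, all(c(m$query, m$members) %in% gene_ids))
      m
    })
  }
  all_members <- unlist(lapply(modules, function(m) c(m$query, m$members)))
  if (anyDuplicated(all_members)) stop("module gene sets must be disjoint")
  structure(
    list(n_genes = n_genes, gene_ids = gene_ids,
         n_treated = n_treated, n_control = n_control,
         modules = modules,
         queries = vapply(modules, `[[`, "", "query"),
         annotation_depth = annotation_depth, noise_sd = noise_sd,
         baseline = baseline, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d vs %d samples, %d module(s), seed %d\n",
              x$n_genes, x$n_treated, x$n_control, length(x$modules), x$seed))
  invisible(x)
}

#' Generate a toy ontology and annotation corpus
#'
#' Builds a rooted DAG in the BP namespace: a layer of shallow terms under
#' the root absorbs the unrelated (noise) genes, and each planted module
#' gets its own chain of `annotation_depth` terms whose deepest term
#' annotates exactly the module's query and members — a specific, high-IC
#' shared annotation. Occasional cross-edges from deep terms to shallow
#' terms make the graph a genuine DAG rather than a tree. Every gene
#' receives at least one curated (`EXP`) annotation, and a random subset
#' additionally receives an `IEA` annotation so evidence filtering has
#' something to remove.
#'
#' @param config A [sim_config].
#' @param n_shallow Number of shallow terms (default scales with the
#'   number of noise genes, at least 6).
#' @param branching Average extra cross-edges per module chain (>= 0).
#' @return List with `graph` (an `ontology_graph`) and `annotations` (an
#'   `annotation_table`).
#' @export
simulate_ontology <- function(config, n_shallow = NULL, branching = 1) {
  stopifnot(inherits(config, "sim_config"), branching >= 0)
  module_genes <- unlist(lapply(config$modules, function(m) c(m$query, m$members)))
  noise_genes <- setdiff(config$gene_ids, module_genes)
  if (is.null(n_shallow)) {
    n_shallow <- max(6L, min(40L, ceiling(length(noise_genes) / 25)))
  }
  stopifnot(n_shallow >= 1)

  .with_seed(config$seed + 1L, {
    counter <- 0L
    new_term <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    root <- new_term()
    shallow <- vapply(seq_len(n_shallow), function(i) new_term(), "")
    parents <- c(stats::setNames(list(character(0)), root),
                 stats::setNames(rep(list(root), n_shallow), shallow))
    deep_terms <- character(0)
    for (m in seq_along(config$modules)) {
      chain_parent <- root
      for (d in seq_len(config$annotation_depth)) {
        t <- new_term()
        parents[[t]] <- chain_parent
        chain_parent <- t
      }
      deep_terms[m] <- chain_parent
      # optional cross-edge: the chain's mid term also descends from a
      # shallow term (keeps the graph a DAG: edge points to a shallower term)
      n_cross <- stats::rpois(1, branching)
      if (n_cross > 0 && config$annotation_depth >= 2) {
        mid <- names(parents)[length(parents) - 1L]
        extra <- sample(shallow, min(n_cross, n_shallow))
        parents[[mid]] <- unique(c(parents[[mid]], extra))
      }
    }
    ids <- names(parents)
    graph <- structure(
      list(terms = data.frame(id = ids,
                              name = paste0("term ", seq_along(ids)),
                              namespace = "BP", stringsAsFactors = FALSE),
           parents = parents,
           alt_id = character(0)),
      class = "ontology_graph"
    )

    ann <- list()
    for (m in seq_along(config$modules)) {
      genes <- c(config$modules[[m]]$query, config$modules[[m]]$members)
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = genes, term_id = deep_terms[m],
        evidence_code = "EXP", namespace = "BP", stringsAsFactors = FALSE)
    }
    if (length(noise_genes)) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = noise_genes,
        term_id = sample(shallow, length(noise_genes), replace = TRUE),
        evidence_code = "EXP", namespace = "BP", stringsAsFactors = FALSE)
    }
    # electronically inferred extras, removable by evidence filtering
    iea_genes <- config$gene_ids[stats::runif(config$n_genes) < 0.2]
    if (length(iea_genes)) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = iea_genes,
        term_id = sample(shallow, length(iea_genes), replace = TRUE),
        evidence_code = "IEA", namespace = "BP", stringsAsFactors = FALSE)
    }
    annotations <- unique(do.call(rbind, ann))
    rownames(annotations) <- NULL
    class(annotations) <- c("annotation_table", "data.frame")
    list(graph = graph, annotations = annotations)
  })
}

#' Generate a two-condition expression matrix with planted modules
#'
#' Module genes follow a single-factor model
#' `x = sqrt(rho) * f_s + sqrt(1 - rho) * e`, giving unit marginal variance
#' and expected pairwise correlation `rho` within the module; treated
#' samples additionally shift module genes by `delta` sd units. Unrelated
#' genes are i.i.d. normal with sd `noise_sd`. All values sit on a log2
#' intensity scale around `baseline`.
#'
#' @param config A [sim_config].
#' @return A labelled [expression_data] object (samples `T1..`, `C1..`,
#'   labels `treated`/`untreated`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_s <- config$n_treated + config$n_control
  sample_ids <- c(sprintf("T%d", seq_len(config$n_treated)),
                  sprintf("C%d", seq_len(config$n_control)))
  labels <- stats::setNames(rep(c("treated", "untreated"),
                                c(config$n_treated, config$n_control)),
                            sample_ids)
  .with_seed(config$seed + 2L, {
    v <- matrix(stats::rnorm(config$n_genes * n_s, sd = config$noise_sd),
                nrow = config$n_genes,
                dimnames = list(config$gene_ids, sample_ids))
    for (m in config$modules) {
      genes <- c(m$query, m$members)
      f <- stats::rnorm(n_s)  # shared latent factor, one draw per sample
      eps <- matrix(stats::rnorm(length(genes) * n_s), nrow = length(genes))
      block <- sqrt(m$rho) * rep(f, each = length(genes)) +
        sqrt(1 - m$rho) * eps
      block <- matrix(block, nrow = length(genes))
      block[, seq_len(config$n_treated)] <-
        block[, seq_len(config$n_treated)] + m$delta
      v[genes, ] <- block
    }
    expression_data(v + config$baseline, labels = labels)
  })
}

#' Generate an interaction network around the planted modules
#'
#' Includes a `fidelity` fraction of the true query-member edges of every
#' module, plus random edges between gene pairs to reach roughly the same
#' edge count as a full-fidelity module network. At `fidelity = 1` every
#' member is adjacent to its query; at `fidelity = 0` the network carries
#' no module information.
#'
#' @param config A [sim_config].
#' @param fidelity Fraction of module edges retained, in `[0, 1]`.
#' @return A [gene_network].
#' @export
simulate_ppi <- function(config, fidelity = 1) {
  stopifnot(inherits(config, "sim_config"), fidelity >= 0, fidelity <= 1)
  .with_seed(config$seed + 3L, {
    edges <- list()
    n_module_edges <- 0L
    for (m in config$modules) {
      n_module_edges <- n_module_edges + length(m$members)
      n_keep <- round(fidelity * length(m$members))
      if (n_keep > 0) {
        keep <- sample(m$members, n_keep)
        edges[[length(edges) + 1L]] <- data.frame(from = m$query, to = keep,
                                                  stringsAsFactors = FALSE)
      }
    }
    n_rand <- n_module_edges
    rnd <- data.frame(
      from = sample(config$gene_ids, 3 * n_rand, replace = TRUE),
      to = sample(config$gene_ids, 3 * n_rand, replace = TRUE),
      stringsAsFactors = FALSE)
    rnd <- rnd[rnd$from != rnd$to, , drop = FALSE]
    rnd <- utils::head(rnd, n_rand)
    edges[[length(edges) + 1L]] <- rnd
    suppressWarnings(gene_network(do.call(rbind, edges),
                                  source_tag = "simulated"))
  })
}

#' Generate a complete synthetic dataset
#'
#' One call producing everything the pipeline consumes: expression matrix
#' with labels, ontology graph and annotation corpus, the fitted
#' per-namespace `ontology_model`, and an interaction network.
#'
#' @param config A [sim_config].
#' @param fidelity Module fidelity of the interaction network.
#' @return List with `expr`, `graph`, `annotations`, `model` (BP
#'   `ontology_model`), `network` and `config`.
#' @export
simulate_dataset <- function(config, fidelity = 1) {
  onto <- simulate_ontology(config)
  list(expr = simulate_expression(config),
       graph = onto$graph,
       annotations = onto$annotations,
       model = build_ontology_model(onto$graph, onto$annotations, "BP"),
       network = simulate_ppi(config, fidelity = fidelity),
       config = config)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Writes the expression TSV (+ labels TSV), OBO ontology, GAF annotation
#' table and edge TSV, all re-readable by the package's readers.
#'
#' @param dataset A list from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    edges = file.path(dir, "edges.tsv")
  )
  write_expression(dataset$expr, paths[["expression"]], paths[["labels"]])
  write_obo(dataset$graph, paths[["obo"]])
  write_gaf(dataset$annotations, paths[["gaf"]])
  utils::write.table(as.data.frame(dataset$network)[, c("from", "to")],
                     paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
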