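# GO-based gene functional similarity: per-term information content from an
# annotation corpus, Lin's term-term similarity through the most informative
# common ancestor (MICA), and gene-level similarity SIM(g_i, g_j) by
# aggregating term-pair similarities over the genes' annotation sets.

#' Build a per-namespace ontology model with information content
#'
#' Restricts the ontology and annotation corpus to one namespace, propagates
#' gene-term annotations up the hierarchy over both `is_a` and `part_of`
#' edges, and derives each term's annotation probability
#' `p(t) =` (distinct genes annotated to `t` or any descendant) / (distinct
#' genes annotated anywhere in the namespace) and information content
#' `IC(t) = -log p(t)` (natural log; the base cancels in Lin's ratio).
#' Terms annotating no gene carry no IC and are unscoreable; the root has
#' `p = 1`, `IC = 0`.
#'
#' @param graph An `ontology_graph` from [read_obo()].
#' @param annotations An `annotation_table` from [read_gaf()] (already
#'   evidence-filtered).
#' @param namespace One of `"BP"`, `"MF"`, `"CC"`.
#' @return An object of class `ontology_model`: list with `namespace`, `ic`
#'   and `p` (named numeric over scoreable terms, `NA` for unannotated
#'   terms), `ancestors` (reflexive ancestor closure per term), `profiles`
#'   (per-gene direct annotation sets `A_i`) and `n_genes` (corpus size).
#' @export
build_ontology_model <- function(graph, annotations, namespace = c("BP", "MF", "CC")) {
  namespace <- match.arg(namespace)
  stopifnot(inherits(graph, "ontology_graph"))
  term_ids <- graph$terms$id[graph$terms$namespace %in% namespace]
  if (!length(term_ids)) stop("ontology has no terms in namespace ", namespace)

  ann <- annotations[annotations$namespace == namespace, , drop = FALSE]
  # resolve alt_id aliases to canonical ids
  if (length(graph$alt_id)) {
    hit <- ann$term_id %in% names(graph$alt_id)
    ann$term_id[hit] <- unname(graph$alt_id[ann$term_id[hit]])
  }
  known <- ann$term_id %in% term_ids
  if (any(!known)) {
    message(sprintf("dropped %d annotation(s) to terms absent from the %s graph",
                    sum(!known), namespace))
    ann <- ann[known, , drop = FALSE]
  }
  if (!nrow(ann)) stop("no annotations in namespace ", namespace)

  parents <- lapply(graph$parents[term_ids], function(p) p[p %in% term_ids])
  ancestors <- .ancestor_closure(term_ids, parents)

  # propagate gene sets from each annotated term to all of its ancestors
  genes_by_term <- new.env(parent = emptyenv())
  direct <- split(ann$gene_id, ann$term_id)
  for (t in names(direct)) {
    for (a in ancestors[[t]]) {
      genes_by_term[[a]] <- c(genes_by_term[[a]], direct[[t]])
    }
  }
  corpus <- unique(ann$gene_id)
  counts <- stats::setNames(rep(0L, length(term_ids)), term_ids)
  for (t in ls(genes_by_term)) {
    counts[[t]] <- length(unique(genes_by_term[[t]]))
  }
  p <- ifelse(counts > 0L, counts / length(corpus), NA_real_)
  ic <- -log(p)
  names(p) <- names(ic) <- term_ids

  profiles <- lapply(split(ann$term_id, ann$gene_id), unique)

  structure(
    list(namespace = namespace, ic = ic, p = p,
         ancestors = ancestors, parents = parents,
         profiles = profiles, n_genes = length(corpus)),
    class = "ontology_model"
  )
}

# Reflexive ancestor closure (each term is its own ancestor), memoized.
.ancestor_closure <- function(term_ids, parents) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    r <- memo[[t]]
    if (!is.null(r)) return(r)
    r <- t
    for (p in parents[[t]]) r <- union(r, get_anc(p))
    memo[[t]] <- r
    r
  }
  out <- lapply(term_ids, get_anc)
  names(out) <- term_ids
  out
}

#' @export
print.ontology_model <- function(x, ...) {
  cat(sprintf("ontology_model [%s]: %d terms (%d scoreable), %d annotated genes\n",
              x$namespace, length(x$ic), sum(!is.na(x$ic)), x$n_genes))
  invisible(x)
}

#' Term information content
#'
#' @param model An `ontology_model`.
#' @param terms Term ids (default: all terms in the model).
#' @return Named numeric vector of IC values (`NA` for unscoreable terms).
#' @export
term_ic <- function(model, terms = NULL) {
  stopifnot(inherits(model, "ontology_model"))
  if (is.null(terms)) return(model$ic)
  out <- model$ic[terms]
  names(out) <- terms
  out
}

.check_scoreable <- function(model, t) {
  if (!(t %in% names(model$ic))) {
    stop("term ", t, " is not in the ", model$namespace, " model")
  }
  if (is.na(model$ic[[t]])) {
    stop("term ", t, " annotates no gene and is unscoreable")
  }
}

#' Most informative common ancestor of two terms
#'
#' The shared (reflexive) ancestor with maximal information content; ties
#' are broken by lexicographically smallest term id for determinism.
#'
#' @param model An `ontology_model`.
#' @param t1,t2 Term ids in the model's namespace.
#' @return The MICA term id, or `NA_character_` if the terms share no
#'   scoreable ancestor.
#' @export
mica <- function(model, t1, t2) {
  stopifnot(inherits(model, "ontology_model"))
  .check_scoreable(model, t1); .check_scoreable(model, t2)
  common <- intersect(model$ancestors[[t1]], model$ancestors[[t2]])
  ics <- model$ic[common]
  common <- common[!is.na(ics)]
  if (!length(common)) return(NA_character_)
  ics <- model$ic[common]
  best <- common[ics == max(ics)]
  sort(best)[1L]
}

#' Lin's term-term semantic similarity
#'
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))`: the information the two
#' terms share (their most informative common ancestor) relative to the
#' information each carries. Identical informative terms score 1; terms
#' whose only common ancestor is the uninformative root score 0, as does a
#' pair of zero-IC terms (no shared information content).
#'
#' @param model An `ontology_model`.
#' @param t1,t2 Term ids; both must be scoreable in the model's namespace.
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(model, t1, t2) {
  stopifnot(inherits(model, "ontology_model"))
  .check_scoreable(model, t1); .check_scoreable(model, t2)
  denom <- model$ic[[t1]] + model$ic[[t2]]
  if (denom == 0) return(0)
  common <- intersect(model$ancestors[[t1]], model$ancestors[[t2]])
  ics <- model$ic[common]
  ics <- ics[!is.na(ics)]
  if (!length(ics)) return(0)
  min(1, max(0, 2 * max(ics) / denom))
}

# Pairwise Lin similarity matrix between two term sets (assumed scoreable).
.lin_matrix <- function(model, terms_i, terms_j) {
  m <- matrix(0, length(terms_i), length(terms_j),
              dimnames = list(terms_i, terms_j))
  for (a in seq_along(terms_i)) {
    for (b in seq_along(terms_j)) {
      m[a, b] <- lin_similarity(model, terms_i[a], terms_j[b])
    }
  }
  m
}

#' Gene-level functional similarity SIM(g_i, g_j)
#'
#' Aggregates Lin term-pair similarities over the genes' annotation sets
#' `A_i`, `A_j`. The default `"max_pair"` aggregation takes the highest
#' between-term similarity over all inter-set pairs;
#' `"best_match_average"` averages each term's best match in the other set,
#' `(sum_a max_b sim + sum_b max_a sim) / (|A_i| + |A_j|)`. Both are
#' symmetric and bounded in `[0, 1]`. A gene with no scoreable annotation
#' in the namespace has undefined similarity (`NA`), which excludes it from
#' candidate pools downstream.
#'
#' @param model An `ontology_model`.
#' @param gene_i,gene_j Gene ids (looked up in the model's annotation
#'   profiles).
#' @param aggregation `"max_pair"` (default) or `"best_match_average"`.
#' @return Similarity in `[0, 1]`, or `NA_real_` when either gene is
#'   unscoreable in the namespace.
#' @export
gene_similarity <- function(model, gene_i, gene_j,
                            aggregation = c("max_pair", "best_match_average")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(model, "ontology_model"))
  ti <- .scoreable_terms(model, gene_i)
  tj <- .scoreable_terms(model, gene_j)
  if (!length(ti) || !length(tj)) return(NA_real_)
  m <- .lin_matrix(model, ti, tj)
  if (aggregation == "max_pair") {
    max(m)
  } else {
    (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) / (nrow(m) + ncol(m))
  }
}

.scoreable_terms <- function(model, gene) {
  t <- model$profiles[[gene]]
  if (is.null(t)) return(character(0))
  t[!is.na(model$ic[t])]
}

#' Genes scoreable in a namespace
#'
#' @param model An `ontology_model`.
#' @return Character vector of gene ids with at least one scoreable
#'   annotation.
#' @export
scoreable_genes <- function(model) {
  stopifnot(inherits(model, "ontology_model"))
  names(model$profiles)[vapply(model$profiles,
                               function(t) any(!is.na(model$ic[t])), TRUE)]
}

#' Batch gene-gene similarity table
#'
#' All-pairs SIM values between two gene sets, as the three-column layout
#' `(gene_i, gene_j, sim)`.
#'
#' @param model An `ontology_model`.
#' @param genes_i,genes_j Gene id vectors (`genes_j` defaults to
#'   `genes_i`).
#' @inheritParams gene_similarity
#' @return Data frame with columns `gene_i`, `gene_j`, `sim` (`NA` for
#'   unscoreable genes).
#' @export
gene_similarity_table <- function(model, genes_i, genes_j = genes_i,
                                  aggregation = c("max_pair", "best_match_average")) {
  aggregation <- match.arg(aggregation)
  grid <- expand.grid(gene_j = genes_j, gene_i = genes_i,
                      stringsAsFactors = FALSE)[, c("gene_i", "gene_j")]
  grid$sim <- mapply(function(a, b) gene_similarity(model, a, b, aggregation),
                     grid$gene_i, grid$gene_j, USE.NAMES = FALSE)
  rownames(grid) <- NULL
  grid
}

#' Write a gene-gene similarity table as TSV
#'
#' @param table Data frame from [gene_similarity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
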