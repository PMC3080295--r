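# Integrated kNN retrieval: per query gene, fuse GO functional similarity
# and absolute Pearson co-expression by their arithmetic mean and rank the
# candidate pool by the fused score.

#' Absolute Pearson correlation between two expression profiles
#'
#' The co-expression component of the integrated score: Pearson's r over
#' pooled samples, mapped from `[-1, 1]` to the unit interval by the
#' absolute value (strong negative co-regulation counts as strong
#' association).
#'
#' @param x,y Numeric vectors of equal length (at least 3 samples).
#' @return `|r|` in `[0, 1]`, or `NA_real_` when either vector is constant
#'   (correlation undefined; the candidate is excluded from ranking).
#' @export
pearson_abs <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  min(1, abs(stats::cor(x, y)))
}

#' Fuse GO similarity and absolute correlation
#'
#' The integrated ranking score: the arithmetic mean
#' `s = (SIM + |r|) / 2` of the two unit-interval components, weighting
#' functional and co-expression evidence equally. Both inputs must already
#' lie in `[0, 1]`; an undefined (`NA`) component makes the fused score
#' undefined, excluding the pair from ranking.
#'
#' @param go_sim,abs_corr Numeric vectors in `[0, 1]` (recycled to equal
#'   length is not supported; lengths must match).
#' @return Vector of fused scores in `[0, 1]` (with `NA` where either
#'   component is `NA`).
#' @export
fuse_scores <- function(go_sim, abs_corr) {
  if (length(go_sim) != length(abs_corr)) stop("component lengths differ")
  ok <- !is.na(go_sim) & !is.na(abs_corr)
  if (any(go_sim[ok] < 0 | go_sim[ok] > 1 | abs_corr[ok] < 0 | abs_corr[ok] > 1)) {
    stop("fused components must lie in [0, 1]")
  }
  (go_sim + abs_corr) / 2
}

#' Retrieve the top-k neighbourhood from a score table
#'
#' Deterministic top-k selection: candidates with undefined scores are
#' dropped, the rest are ordered by fused score descending with ties broken
#' by ascending gene id, and the first `min(k, pool size)` are returned —
#' exactly the k-prefix of the full descending sort.
#'
#' @param scores Data frame with columns `gene` and `fused` (extra columns
#'   such as `go_sim` and `abs_corr` are carried through).
#' @param k Positive integer neighbourhood size.
#' @return Data frame of at most `k` rows, ordered, with a leading `rank`
#'   column. A warning is raised when the eligible pool is empty.
#' @export
retrieve_neighbors <- function(scores, k) {
  stopifnot(is.data.frame(scores), all(c("gene", "fused") %in% names(scores)))
  if (!.is_count(k)) stop("`k` must be a positive integer")
  scores <- scores[!is.na(scores$fused), , drop = FALSE]
  if (!nrow(scores)) {
    warning("empty candidate pool; returning empty neighbourhood")
    return(cbind(rank = integer(0), scores))
  }
  ord <- order(-scores$fused, scores$gene, method = "radix")  # C-locale ties
  out <- scores[ord[seq_len(min(k, nrow(scores)))], , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Fit an integrated kNN neighbourhood model
#'
#' For each query gene, computes the GO-based functional similarity `SIM`
#' and absolute Pearson co-expression `|r|` against every eligible
#' candidate gene, fuses them by their arithmetic mean, and retrieves the
#' `k` top-ranked genes as the query's neighbourhood. The candidate pool is
#' the set of genes present in the (standardized) expression matrix that
#' carry at least one scoreable annotation in the model's namespace; the
#' query itself is always excluded, other query genes remain eligible.
#' Queries missing from the expression matrix or without scoreable
#' annotations are skipped with a warning.
#'
#' @param expr An [expression_data] object (standardized on the fly if
#'   needed; zero-variance rows are excluded).
#' @param ontology An `ontology_model` from [build_ontology_model()].
#' @param queries Character vector of query gene ids.
#' @param k Neighbourhood size (typical analyses sweep 1..20).
#' @param aggregation Term-set aggregation passed to [gene_similarity()].
#' @return An object of class `iknn`: list with `queries` (those actually
#'   fitted), `dropped_queries`, `k`, `aggregation`, `namespace`,
#'   `pool_size`, `scores` (per query, the full ranked candidate table with
#'   columns `rank`, `gene`, `go_sim`, `abs_corr`, `fused`) and
#'   `neighborhoods` (the k-prefix of each).
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 60, module_size = 5, seed = 1))
#' fit <- iknn(sim$expr, sim$model, queries = sim$config$queries, k = 5)
#' fit
#' head(fit$neighborhoods[[1]])
#' @export
iknn <- function(expr, ontology, queries, k = 15,
                 aggregation = c("max_pair", "best_match_average")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(expr, "expression_data"),
            inherits(ontology, "ontology_model"))
  if (!.is_count(k)) stop("`k` must be a positive integer")
  queries <- unique(as.character(queries))
  expr <- standardize_expression(expr)
  v <- expr$values

  annotated <- scoreable_genes(ontology)
  eligible <- intersect(rownames(v), annotated)

  dropped <- character(0)
  scores <- list()
  for (q in queries) {
    if (!(q %in% rownames(v))) {
      warning("query '", q, "' absent from the expression matrix; skipped")
      dropped <- c(dropped, q)
      next
    }
    if (!(q %in% annotated)) {
      warning("query '", q, "' has no scoreable ", ontology$namespace,
              " annotation; skipped")
      dropped <- c(dropped, q)
      next
    }
    pool <- setdiff(eligible, q)
    if (!length(pool)) {
      warning("query '", q, "' has an empty candidate pool")
      dropped <- c(dropped, q)
      next
    }
    go_sim <- vapply(pool, function(g)
      gene_similarity(ontology, q, g, aggregation), numeric(1))
    abs_corr <- abs(as.vector(stats::cor(t(v[pool, , drop = FALSE]), v[q, ])))
    abs_corr <- pmin(abs_corr, 1)
    tab <- data.frame(gene = pool, go_sim = unname(go_sim),
                      abs_corr = abs_corr,
                      fused = fuse_scores(unname(go_sim), abs_corr),
                      stringsAsFactors = FALSE)
    ranked <- retrieve_neighbors(tab, k = max(k, nrow(tab)))
    scores[[q]] <- ranked
  }
  if (!length(scores)) stop("no query could be scored")

  structure(
    list(queries = names(scores), dropped_queries = dropped,
         k = k, aggregation = aggregation,
         namespace = ontology$namespace,
         pool_size = length(eligible),
         scores = scores,
         neighborhoods = lapply(scores, utils::head, n = k),
         call = match.call()),
    class = "iknn"
  )
}

#' @export
print.iknn <- function(x, ...) {
  cat(sprintf("Integrated kNN fit (%s, %s aggregation)\n",
              x$namespace, x$aggregation))
  cat(sprintf("  %d quer%s, k = %d, candidate pool of %d annotated genes\n",
              length(x$queries), if (length(x$queries) == 1L) "y" else "ies",
              x$k, x$pool_size))
  if (length(x$dropped_queries)) {
    cat("  dropped queries:", paste(x$dropped_queries, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.iknn <- function(object, ...) {
  rows <- lapply(object$queries, function(q) {
    nb <- object$neighborhoods[[q]]
    data.frame(query = q, n_neighbors = nrow(nb),
               top_neighbor = if (nrow(nb)) nb$gene[1L] else NA_character_,
               top_fused = if (nrow(nb)) nb$fused[1L] else NA_real_,
               mean_fused = if (nrow(nb)) mean(nb$fused) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.iknn", "data.frame")
  out
}

#' @export
print.summary.iknn <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  y$top_fused <- round(y$top_fused, digits)
  y$mean_fused <- round(y$mean_fused, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.iknn <- function(x, ...) {
  long <- as.data.frame(x)
  stripchart(fused ~ query, data = long, vertical = TRUE, method = "jitter",
             pch = 16, cex = 0.7, col = "grey40",
             ylab = "fused score (SIM + |r|)/2",
             main = sprintf("Integrated kNN neighbourhoods (k = %d)", x$k), ...)
  invisible(x)
}

#' @export
as.data.frame.iknn <- function(x, ...) {
  out <- do.call(rbind, lapply(x$queries, function(q) {
    cbind(query = q, x$neighborhoods[[q]])
  }))
  rownames(out) <- NULL
  out
}

#' Weighted query-neighbour network from an integrated kNN fit
#'
#' One edge per retrieved (query, neighbour) pair, weighted by the fused
#' score — the network rendering of the fitted neighbourhoods, suitable for
#' [export_network()].
#'
#' @param x An [iknn] fit.
#' @return A [gene_network] with a `weight` column.
#' @export
as_network <- function(x) {
  stopifnot(inherits(x, "iknn"))
  long <- as.data.frame(x)
  gene_network(long[, c("query", "gene", "fused")], source_tag = "iknn")
}

#' Overlap between two sets of query neighbourhoods
#'
#' For each query and each neighbourhood size `k`, counts the genes shared
#' between the two methods' neighbourhoods, and tests the per-query counts
#' against the null hypothesis that the mean number of shared neighbours is
#' zero (two-sided one-sample t-test). Ranked sources ([iknn] fits) are cut
#' at each `k`; unranked sources (named lists of gene sets, e.g. PPI
#' partner sets) are used whole.
#'
#' @param a,b [iknn] fits or named lists of character vectors keyed by
#'   query.
#' @param k Integer vector of neighbourhood sizes to evaluate (default
#'   `1:20`).
#' @return An object of class `overlap_summary`: list with `counts` (query
#'   x k matrix of shared-gene counts) and `summary` (data frame of `k`,
#'   `mean_shared`, `t_stat`, `p_value`).
#' @export
neighborhood_overlap <- function(a, b, k = 1:20) {
  stopifnot(all(k >= 1), all(k == floor(k)))
  qa <- .query_names(a); qb <- .query_names(b)
  queries <- intersect(qa, qb)
  if (!length(queries)) stop("the two methods share no query")
  if (!setequal(qa, qb)) {
    warning("query sets differ; using the ", length(queries),
            " shared quer", if (length(queries) == 1L) "y" else "ies")
  }
  counts <- matrix(0L, nrow = length(queries), ncol = length(k),
                   dimnames = list(queries, as.character(k)))
  for (i in seq_along(k)) {
    for (q in queries) {
      counts[q, i] <- length(intersect(.top_set(a, q, k[i]),
                                       .top_set(b, q, k[i])))
    }
  }
  summ <- do.call(rbind, lapply(seq_along(k), function(i) {
    tt <- .t_test_zero(counts[, i])
    data.frame(k = k[i], mean_shared = tt$mean, t_stat = tt$t,
               p_value = tt$p)
  }))
  structure(list(counts = counts, summary = summ),
            class = "overlap_summary")
}

.query_names <- function(x) {
  if (inherits(x, "iknn")) x$queries else names(x)
}

.top_set <- function(x, q, k) {
  if (inherits(x, "iknn")) {
    utils::head(x$scores[[q]]$gene, k)
  } else {
    x[[q]]
  }
}

#' @export
print.overlap_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Neighbourhood overlap over %d queries\n", nrow(x$counts)))
  print(transform(x$summary,
                  mean_shared = round(mean_shared, digits),
                  t_stat = round(t_stat, digits),
                  p_value = signif(p_value, digits)),
        row.names = FALSE)
  invisible(x)
}
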