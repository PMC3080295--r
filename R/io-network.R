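#' Gene interaction / similarity network container
#'
#' Stores an undirected network as a set of unordered gene-id pairs with an
#' optional edge weight. Self-loops are rejected and reversed duplicates are
#' collapsed (keeping the first weight seen).
#'
#' @param edges Data frame whose first two columns are gene ids and whose
#'   optional third column is a numeric weight.
#' @param source_tag Free-text provenance recorded on the object.
#' @return An object of class `gene_network`: data frame with columns
#'   `from`, `to` and optionally `weight`, plus a `source_tag` attribute.
#' @export
gene_network <- function(edges, source_tag = "user") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs at least two columns")
  out <- data.frame(from = as.character(edges[[1L]]),
                    to = as.character(edges[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(edges) >= 3L) out$weight <- as.numeric(edges[[3L]])
  loops <- out$from == out$to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    out <- out[!loops, , drop = FALSE]
  }
  key <- paste(pmin(out$from, out$to), pmax(out$from, out$to), sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, source_tag = source_tag,
            class = c("gene_network", "data.frame"))
}

#' Read a two- or three-column edge list
#'
#' Reads a headerless TSV of `gene <TAB> gene [<TAB> weight]` lines, e.g. a
#' pre-merged table of experimentally validated protein-protein
#' interactions. Self-loops are dropped with a warning and unordered
#' duplicate pairs are collapsed.
#'
#' @param path Path to the edge TSV.
#' @param source_tag Provenance string stored on the network; defaults to
#'   the file name.
#' @return A [gene_network].
#' @export
read_edges <- function(path, source_tag = basename(path)) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) >= 3L) df[[3L]] <- as.numeric(df[[3L]])
  gene_network(df[, seq_len(min(3L, ncol(df))), drop = FALSE],
               source_tag = source_tag)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network (%s): %d edges over %d genes\n",
              attr(x, "source_tag"), nrow(x),
              length(unique(c(x$from, x$to)))))
  invisible(x)
}

#' Direct interaction partners of a gene
#'
#' The distance-1 neighbourhood of `gene` in an interaction network — the
#' classical guilt-by-association neighbourhood used as a baseline against
#' integrated kNN retrieval. A gene absent from the network has an empty
#' neighbourhood.
#'
#' @param network A [gene_network].
#' @param gene Gene id.
#' @return Character vector of partner gene ids (sorted, unique).
#' @export
ppi_neighbors <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"), length(gene) == 1L)
  sort(unique(c(network$to[network$from == gene],
                network$from[network$to == gene])))
}

#' Export a network in SIF or GraphML format
#'
#' SIF (`node relation node`) is the plain-text dialect understood by most
#' network viewers; GraphML (written through igraph) preserves edge weights.
#'
#' @param x A [gene_network] or an [iknn] fit (exported as its weighted
#'   query-neighbour network).
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @param relation Relation label used for SIF lines.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("sif", "graphml"),
                           relation = "sim") {
  format <- match.arg(format)
  if (inherits(x, "iknn")) x <- as_network(x)
  stopifnot(inherits(x, "gene_network"))
  if (format == "sif") {
    writeLines(paste(x$from, relation, x$to, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(as.data.frame(x), directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network from a SIF file
#'
#' @param path Path to a SIF file (`node relation node` per line).
#' @param source_tag Provenance string; defaults to the file name.
#' @return A [gene_network] (relation column discarded).
#' @export
read_sif <- function(path, source_tag = basename(path)) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) < 3L) stop("SIF lines must be 'node relation node'")
  gene_network(df[, c(1L, 3L)], source_tag = source_tag)
}
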