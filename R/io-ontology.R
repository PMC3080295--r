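# Readers and writers for the two Gene Ontology interchange formats the
# package consumes: OBO term stanzas and GAF 2.x annotation tables. No OBO
# or GAF reader ships with the installed R stack, and both are line-oriented
# text formats, so they are parsed here directly.

.NAMESPACE_MAP <- c(biological_process = "BP",
                    molecular_function = "MF",
                    cellular_component = "CC")

# GO evidence codes recognised by read_gaf(); anything else marks the line
# as malformed.
.GO_EVIDENCE_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
                        "HTP", "HDA", "HMP", "HGI", "HEP",
                        "IBA", "IBD", "IKR", "IRD",
                        "ISS", "ISO", "ISA", "ISM", "IGC", "RCA",
                        "TAS", "NAS", "IC", "ND", "IEA")

#' Read an ontology in OBO format
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file into a per-namespace
#' directed acyclic graph. Both `is_a` and `relationship: part_of` links are
#' kept as parent edges, obsolete terms are excluded, and `alt_id` aliases
#' are recorded so annotation files using superseded ids can be resolved.
#' A cycle among the retained terms is an error that reports one offending
#' cycle.
#'
#' @param path Path to the OBO file.
#' @return An object of class `ontology_graph`: list with `terms` (data
#'   frame of `id`, `name`, `namespace` in BP/MF/CC coding), `parents`
#'   (named list of parent term ids) and `alt_id` (named character vector
#'   mapping alias to canonical id).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0); names_ <- character(0); ns <- character(0)
  parents <- list(); alt <- character(0)
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    chunk <- lines[(starts[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk)]
    field <- sub(":.*$", "", chunk)
    value <- sub("^[^:]+:\\s*", "", chunk)
    value <- sub("\\s*!.*$", "", value)  # trailing comments
    id <- value[field == "id"][1L]
    if (is.na(id)) next
    if (any(field == "is_obsolete" & value == "true")) next
    nm <- value[field == "name"][1L]
    namespace <- value[field == "namespace"][1L]
    isa <- value[field == "is_a"]
    rel <- value[field == "relationship"]
    partof <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    alts <- value[field == "alt_id"]
    ids <- c(ids, id)
    names_ <- c(names_, if (is.na(nm)) id else nm)
    ns <- c(ns, if (is.na(namespace)) NA_character_ else
      unname(.NAMESPACE_MAP[namespace]))
    parents[[id]] <- unique(c(isa, partof))
    if (length(alts)) alt[alts] <- id
  }
  if (!length(ids)) stop("no usable [Term] stanzas in OBO file: ", path)
  # keep only edges between retained (non-obsolete) terms
  parents <- lapply(parents, function(p) p[p %in% ids])

  cyc <- .find_cycle(parents)
  if (!is.null(cyc)) {
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  structure(
    list(terms = data.frame(id = ids, name = names_, namespace = ns,
                            stringsAsFactors = FALSE),
         parents = parents,
         alt_id = alt),
    class = "ontology_graph"
  )
}

# Depth-first search for a directed cycle along child -> parent edges.
# Returns the cycle as a vector of term ids, or NULL when acyclic.
.find_cycle <- function(parents) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  found <- NULL
  visit <- function(t, trail) {
    st <- state[[t]]
    if (!is.null(st)) {
      if (st == 1L) {
        i <- match(t, trail)
        found <<- c(trail[i:length(trail)], t)
        return(TRUE)
      }
      return(FALSE)
    }
    state[[t]] <- 1L
    for (p in parents[[t]]) {
      if (visit(p, c(trail, t))) return(TRUE)
    }
    state[[t]] <- 2L
    FALSE
  }
  for (t in names(parents)) {
    if (is.null(state[[t]]) && visit(t, character(0))) break
  }
  found
}

#' @export
print.ontology_graph <- function(x, ...) {
  tab <- table(x$terms$namespace, useNA = "ifany")
  cat(sprintf("ontology_graph: %d terms (%s), %d parent edges\n",
              nrow(x$terms),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              sum(lengths(x$parents))))
  invisible(x)
}

#' Write an ontology graph in OBO format
#'
#' Minimal OBO 1.2 writer used by the synthetic-data generator; output is
#' re-readable by [read_obo()].
#'
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  inv_ns <- stats::setNames(names(.NAMESPACE_MAP), .NAMESPACE_MAP)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", inv_ns[[graph$terms$namespace[i]]]),
             paste0("is_a: ", graph$parents[[id]]),
             "")
    writeLines(out, con)
  }
  invisible(path)
}

#' Read gene annotations in GAF 2.x format
#'
#' Keeps `(gene symbol, GO id, evidence code, namespace)` tuples. Records
#' whose qualifier contains `NOT` are dropped, as are records carrying an
#' excluded evidence code — by default `IEA`, restricting the corpus to
#' curated (non-electronically-inferred) annotations. Lines with too few
#' columns or an unrecognised evidence/aspect code are skipped and counted.
#'
#' @param path Path to the GAF file (`!` comment lines are ignored).
#' @param exclude_evidence Character vector of evidence codes to drop;
#'   defaults to `"IEA"`. Use `character(0)` to keep everything.
#' @return A data frame of class `annotation_table` with columns `gene_id`,
#'   `term_id`, `evidence_code`, `namespace` (BP/MF/CC).
#' @export
read_gaf <- function(path, exclude_evidence = "IEA") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  empty <- data.frame(gene_id = character(0), term_id = character(0),
                      evidence_code = character(0), namespace = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("annotation_table", "data.frame")
  if (!length(lines)) {
    warning("empty annotation file: ", path)
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_malformed <- 0L
  rows <- vector("list", length(fields))
  aspect_map <- c(P = "BP", F = "MF", C = "CC")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 9L) { n_malformed <- n_malformed + 1L; next }
    evidence <- f[7L]; aspect <- f[9L]
    if (!(evidence %in% .GO_EVIDENCE_CODES) || !(aspect %in% names(aspect_map))) {
      n_malformed <- n_malformed + 1L
      next
    }
    if (grepl("\\bNOT\\b", f[4L])) next
    if (evidence %in% exclude_evidence) next
    rows[[i]] <- c(f[3L], f[5L], evidence, unname(aspect_map[aspect]))
  }
  if (n_malformed) {
    warning(sprintf("skipped %d malformed annotation line(s)", n_malformed))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no usable annotation records in: ", path)
    return(empty)
  }
  m <- do.call(rbind, rows)
  out <- data.frame(gene_id = m[, 1L], term_id = m[, 2L],
                    evidence_code = m[, 3L], namespace = m[, 4L],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table in GAF 2.2 format
#'
#' Inverse of [read_gaf()] for the columns this package uses; the remaining
#' GAF columns are filled with placeholders.
#'
#' @param annotations An `annotation_table` (or data frame with columns
#'   `gene_id`, `term_id`, `evidence_code`, `namespace`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  aspect <- c(BP = "P", MF = "F", CC = "C")[annotations$namespace]
  lines <- sprintf(
    "SYN\t%s\t%s\t\t%s\tSYN:ref\t%s\t\t%s\t%s\t\tgene\ttaxon:9606\t20110330\tSYN\t\t",
    annotations$gene_id, annotations$gene_id, annotations$term_id,
    annotations$evidence_code, aspect, annotations$gene_id
  )
  writeLines(c("!gaf-version: 2.2", lines), path)
  invisible(path)
}
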