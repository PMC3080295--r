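# Shared fixtures and independent oracles. Fixtures are written to
# tempfiles at test time; oracles deliberately re-derive quantities by
# brute force, independently of the package's code paths.

# --- toy ontology ---------------------------------------------------------
# root GO:1 <- parent GO:2 <- siblings GO:3, GO:4; shallow GO:5 (alt id
# GO:99); GO:6 is obsolete.
write_toy_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: parent",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: sib1",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: sib2",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000005", "name: shallow",
    "namespace: biological_process", "alt_id: GO:0000099",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000006", "name: gone",
    "namespace: biological_process", "is_a: GO:0000001",
    "is_obsolete: true", ""
  ), path)
  path
}

# Corpus of 4 genes with one annotation each: p(GO:3) = p(GO:4) = 0.25,
# p(GO:2) = p(GO:5) = 0.5, p(root) = 1.
toy_annotations <- function() {
  structure(
    data.frame(
      gene_id = c("gA", "gB", "gC", "gD"),
      term_id = c("GO:0000003", "GO:0000004", "GO:0000005", "GO:0000005"),
      evidence_code = "IDA", namespace = "BP",
      stringsAsFactors = FALSE),
    class = c("annotation_table", "data.frame"))
}

toy_model <- function() {
  graph <- read_obo(write_toy_obo())
  build_ontology_model(graph, toy_annotations(), "BP")
}

# --- random ontologies for oracle-equivalence tests -----------------------
# A random DAG of <= n_terms BP terms (term i >= 2 draws 1-2 parents among
# earlier terms) with 12 genes annotated to 1-3 random non-root terms.
random_ontology <- function(n_terms = 30, n_genes = 12, seed = 1) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[ids[1]]] <- character(0)
  for (i in 2:n_terms) {
    k <- sample(1:2, 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], min(k, i - 1))
  }
  graph <- structure(
    list(terms = data.frame(id = ids, name = ids, namespace = "BP",
                            stringsAsFactors = FALSE),
         parents = parents, alt_id = character(0)),
    class = "ontology_graph")
  genes <- sprintf("g%02d", seq_len(n_genes))
  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g,
               term_id = sample(ids[-1], sample(1:3, 1)),
               evidence_code = "IDA", namespace = "BP",
               stringsAsFactors = FALSE)
  }))
  class(ann) <- c("annotation_table", "data.frame")
  list(graph = graph, annotations = ann,
       model = build_ontology_model(graph, ann, "BP"))
}

# --- independent oracles --------------------------------------------------

# Ancestors of a term by naive repeated parent expansion (reflexive).
oracle_ancestors <- function(parents, t) {
  seen <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# MICA by exhaustive enumeration of all common ancestors.
oracle_mica <- function(model, t1, t2) {
  common <- intersect(oracle_ancestors(model$parents, t1),
                      oracle_ancestors(model$parents, t2))
  ics <- model$ic[common]
  common <- common[!is.na(ics)]
  if (!length(common)) return(NA_character_)
  ics <- model$ic[common]
  best <- common[ics == max(ics)]
  sort(best)[1]
}

# Top-k retrieval by a full descending sort of the whole pool.
oracle_topk <- function(scores, k) {
  scores <- scores[!is.na(scores$fused), , drop = FALSE]
  ord <- order(-scores$fused, scores$gene, method = "radix")
  out <- scores[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# AUC by exhaustive enumeration of all positive-negative score pairs.
oracle_auc_pairs <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Area under a (fpr, tpr) step curve by the trapezoidal rule.
oracle_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# --- small expression fixture ---------------------------------------------
write_toy_expression <- function(path = tempfile(fileext = ".tsv"),
                                 rows = NULL) {
  if (is.null(rows)) {
    rows <- c("gene\ts1\ts2\ts3\ts4",
              "g1\t1\t2\t3\t4",
              "g2\t2\t1\t4\t3",
              "g3\t0.5\t0.5\t0.7\t0.9")
  }
  writeLines(rows, path)
  path
}

toy_labels <- c(s1 = "treated", s2 = "treated",
                s3 = "untreated", s4 = "untreated")
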