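# File readers and writers: expression TSV, OBO, GAF, edge lists, SIF.

test_that("expression TSV parses with labels attached", {
  x <- read_expression(write_toy_expression(), labels = toy_labels)
  expect_s3_class(x, "expression_data")
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(rownames(x$values), c("g1", "g2", "g3"))
  expect_equal(as.character(x$labels),
               c("treated", "treated", "untreated", "untreated"))
  expect_equal(levels(x$labels), c("untreated", "treated"))
  expect_equal(unname(x$values["g1", ]), c(1, 2, 3, 4))
})

test_that("duplicate gene rows collapse by averaging", {
  p <- write_toy_expression(rows = c(
    "gene\ts1\ts2", "g1\t1\t2", "g1\t1\t2", "g2\t0\t4"))
  expect_message(x <- read_expression(p), "collapsed 1 duplicated")
  expect_equal(dim(x), c(2L, 2L))
  expect_equal(unname(x$values["g1", ]), c(1, 2))

  p2 <- write_toy_expression(rows = c(
    "gene\ts1\ts2", "g1\t1\t2", "g1\t3\t2", "g2\t0\t4"))
  expect_warning(
    expect_message(x2 <- read_expression(p2), "collapsed"),
    "conflicting duplicate rows.*g1")
  expect_equal(unname(x2$values["g1", ]), c(2, 2))
})

test_that("non-numeric and missing cells are reported by coordinate", {
  p <- write_toy_expression(rows = c("gene\ts1\ts2", "g1\t1\tfoo"))
  expect_error(read_expression(p), "foo.*g1.*s2")
  p2 <- write_toy_expression(rows = c("gene\ts1\ts2", "g1\t1\t", "g2\t2\t3"))
  expect_error(read_expression(p2), "missing value.*g1.*s2")
  x <- read_expression(p2, impute = TRUE)
  expect_equal(unname(x$values["g1", ]), c(1, 1))  # per-gene mean
})

test_that("expression round trip reproduces the object", {
  x <- read_expression(write_toy_expression(), labels = toy_labels)
  p <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(x, p, lp)
  y <- read_expression(p, labels = lp)
  expect_equal(y$values, x$values)
  expect_equal(y$labels, x$labels)
})

test_that("OBO parsing keeps the DAG, drops obsoletes, maps alt ids", {
  g <- read_obo(write_toy_obo())
  expect_equal(nrow(g$terms), 5L)             # obsolete GO:6 excluded
  expect_equal(sum(lengths(g$parents)), 4L)   # 4 is_a edges
  expect_false("GO:0000006" %in% g$terms$id)
  expect_equal(unname(g$alt_id[["GO:0000099"]]), "GO:0000005")
  expect_equal(g$parents[["GO:0000003"]], "GO:0000002")
})

test_that("a cyclic ontology is rejected with a reported cycle", {
  p <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: GO:0000001", "name: a",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "name: b",
    "namespace: biological_process", "is_a: GO:0000001", ""
  ), p)
  expect_error(read_obo(p), "cycle.*GO:0000001")
})

test_that("OBO round trip through write_obo preserves the graph", {
  g <- read_obo(write_toy_obo())
  p <- tempfile(fileext = ".obo")
  write_obo(g, p)
  g2 <- read_obo(p)
  expect_equal(g2$terms[c("id", "namespace")], g$terms[c("id", "namespace")])
  expect_equal(g2$parents, g$parents)
})

test_that("GAF records are evidence- and qualifier-filtered", {
  p <- tempfile(fileext = ".gaf")
  gaf_line <- function(gene, term, ev, aspect = "P", qual = "") {
    paste("DB", gene, gene, qual, term, "ref", ev, "", aspect,
          gene, "", "gene", "taxon:9606", "20110101", "DB", "", "",
          sep = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               gaf_line("gA", "GO:0000003", "IDA"),
               gaf_line("gB", "GO:0000004", "TAS"),
               gaf_line("gC", "GO:0000005", "IEA"),
               gaf_line("gD", "GO:0000005", "EXP")), p)
  tab <- read_gaf(p)
  expect_equal(nrow(tab), 3L)                 # IEA dropped
  expect_false("gC" %in% tab$gene_id)
  expect_equal(nrow(read_gaf(p, exclude_evidence = character(0))), 4L)

  writeLines(c(gaf_line("gA", "GO:0000003", "IDA", qual = "NOT|involved_in"),
               gaf_line("gB", "GO:0000004", "IDA")), p)
  expect_equal(read_gaf(p)$gene_id, "gB")     # NOT-qualified dropped

  writeLines(c(gaf_line("gA", "GO:0000003", "IDA"), "broken\tline"), p)
  expect_warning(tab3 <- read_gaf(p), "skipped 1 malformed")
  expect_equal(nrow(tab3), 1L)

  writeLines("!gaf-version: 2.2", p)
  expect_warning(empty <- read_gaf(p), "empty|no usable")
  expect_equal(nrow(empty), 0L)
})

test_that("GAF round trip through write_gaf preserves the records", {
  tab <- toy_annotations()
  p <- tempfile(fileext = ".gaf")
  write_gaf(tab, p)
  tab2 <- read_gaf(p, exclude_evidence = character(0))
  expect_equal(tab2[order(tab2$gene_id), ], tab[order(tab$gene_id), ],
               ignore_attr = TRUE)
})

test_that("edge lists drop self-loops and reversed duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "c\td"), p)
  net <- read_edges(p)
  expect_equal(nrow(net), 2L)

  writeLines(c("a\ta", "c\td"), p)
  expect_warning(net2 <- read_edges(p), "self-loop")
  expect_equal(nrow(net2), 1L)
})

test_that("SIF export then re-read yields an identical edge set", {
  net <- gene_network(data.frame(from = c("a", "c", "x"),
                                 to = c("b", "d", "y")))
  p <- tempfile(fileext = ".sif")
  export_network(net, p, "sif")
  net2 <- read_sif(p)
  key <- function(n) sort(paste(pmin(n$from, n$to), pmax(n$from, n$to)))
  expect_identical(key(net2), key(net))
})

test_that("GraphML export is readable by igraph with weights intact", {
  net <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d"),
                                 weight = c(0.5, 0.9)))
  p <- tempfile(fileext = ".graphml")
  export_network(net, p, "graphml")
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$weight, c(0.5, 0.9))
})

test_that("loaders are deterministic across repeated reads", {
  p <- write_toy_expression()
  expect_identical(read_expression(p), read_expression(p))
  o <- write_toy_obo()
  expect_identical(read_obo(o), read_obo(o))
})
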