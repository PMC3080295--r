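# Standardization, co-expression, score fusion, top-k retrieval, the iknn
# fit, PPI baseline neighbourhoods and overlap statistics.

test_that("standardization gives mean 0, sd 1 rows and is idempotent", {
  v <- rbind(g1 = c(1, 2, 3), g2 = c(10, 0, 5))
  colnames(v) <- paste0("s", 1:3)
  x <- standardize_expression(expression_data(v))
  expect_true(all(abs(rowMeans(x$values)) < 1e-9))
  expect_true(all(abs(apply(x$values, 1, sd) - 1) < 1e-9))
  expect_identical(standardize_expression(x), x)
})

test_that("zero-variance rows are flagged and excluded", {
  v <- rbind(g1 = c(1, 2, 3), flat = c(2, 2, 2))
  colnames(v) <- paste0("s", 1:3)
  expect_warning(x <- standardize_expression(expression_data(v)),
                 "zero-variance.*flat")
  expect_equal(rownames(x$values), "g1")
})

test_that("absolute Pearson correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_abs(x, 2 * x + 1), 1)
  expect_equal(pearson_abs(x, -x), 1)
  y <- c(1, 2, 3, 100)
  hand <- abs(sum((x - mean(x)) * (y - mean(y))) /
                sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(pearson_abs(x, y), hand, tolerance = 1e-12)
  expect_true(is.na(pearson_abs(x, rep(1, 4))))
  expect_error(pearson_abs(1:2, 1:2), "at least 3")
})

test_that("fused score is the exact arithmetic mean of its components", {
  expect_identical(fuse_scores(1, 1), 1)
  expect_identical(fuse_scores(0, 0), 0)
  expect_identical(fuse_scores(0.6, 0.8), 0.7)
  expect_true(is.na(fuse_scores(NA_real_, 0.5)))
  expect_error(fuse_scores(1.2, 0.5), "\\[0, 1\\]")
})

test_that("top-k retrieval equals the prefix of a brute-force full sort", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    scores <- data.frame(
      gene = sprintf("g%03d", sample(n)),
      fused = sample(round(runif(n), 2)),  # rounded scores force ties
      stringsAsFactors = FALSE)
    scores$fused[sample(n, 3)] <- NA
    for (k in c(1, 5, n + 10)) {
      got <- retrieve_neighbors(scores, k)
      want <- oracle_topk(scores, k)
      expect_equal(got$gene, want$gene)
      expect_equal(got$fused, want$fused)
      expect_equal(got$rank, seq_len(nrow(got)))
    }
  }
})

test_that("retrieval ties break by ascending gene id", {
  scores <- data.frame(gene = c("z", "a", "m"), fused = c(0.5, 0.5, 0.9))
  got <- retrieve_neighbors(scores, 3)
  expect_equal(got$gene, c("m", "a", "z"))
})

test_that("k beyond the pool returns the whole pool; empty pool warns", {
  scores <- data.frame(gene = c("a", "b"), fused = c(0.2, 0.4))
  expect_equal(nrow(retrieve_neighbors(scores, 10)), 2L)
  empty <- data.frame(gene = "a", fused = NA_real_)
  expect_warning(out <- retrieve_neighbors(empty, 3), "empty candidate pool")
  expect_equal(nrow(out), 0L)
})

test_that("raising k extends a neighbourhood without reordering it", {
  set.seed(4)
  scores <- data.frame(gene = sprintf("g%02d", 1:50),
                       fused = round(runif(50), 2))
  prev <- retrieve_neighbors(scores, 1)$gene
  for (k in 2:20) {
    cur <- retrieve_neighbors(scores, k)$gene
    expect_identical(cur[seq_along(prev)], prev)
    prev <- cur
  }
})

test_that("excluding a candidate preserves the order of the rest", {
  set.seed(9)
  scores <- data.frame(gene = sprintf("g%02d", 1:30),
                       fused = round(runif(30), 2))
  full <- retrieve_neighbors(scores, 30)$gene
  drop <- full[7]
  scores$fused[scores$gene == drop] <- NA  # undefined component
  reduced <- retrieve_neighbors(scores, 30)$gene
  expect_identical(reduced, setdiff(full, drop))
})

test_that("iknn fits ranked neighbourhoods that exclude the query", {
  ds <- simulate_dataset(sim_config(n_genes = 80, n_modules = 2,
                                    module_size = 6, seed = 21))
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 6)
  expect_s3_class(fit, "iknn")
  expect_equal(fit$queries, ds$config$queries)
  for (q in fit$queries) {
    nb <- fit$neighborhoods[[q]]
    expect_equal(nrow(nb), 6L)
    expect_false(q %in% nb$gene)
    expect_equal(nb$fused, (nb$go_sim + nb$abs_corr) / 2, tolerance = 1e-12)
    expect_true(all(diff(nb$fused) <= 0))
    # neighbourhood is the k-prefix of the full ranking
    expect_identical(nb$gene, head(fit$scores[[q]]$gene, 6))
  }
  # other queries remain eligible as neighbours (no cross-query exclusion)
  expect_true(all(vapply(fit$queries, function(q)
    !(q %in% fit$neighborhoods[[q]]$gene), TRUE)))
})

test_that("queries without expression or annotation are skipped", {
  ds <- simulate_dataset(sim_config(n_genes = 60, n_modules = 1,
                                    module_size = 5, seed = 22))
  expect_warning(
    fit <- iknn(ds$expr, ds$model, c(ds$config$queries, "NOPE"), k = 3),
    "absent from the expression matrix")
  expect_equal(fit$dropped_queries, "NOPE")
})

test_that("PPI neighbourhoods are the distance-1 partners", {
  star <- gene_network(data.frame(from = "hub", to = paste0("leaf", 1:4)))
  expect_setequal(ppi_neighbors(star, "hub"), paste0("leaf", 1:4))
  expect_equal(ppi_neighbors(star, "absent"), character(0))
  tri <- gene_network(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a")))
  expect_setequal(ppi_neighbors(tri, "a"), c("b", "c"))
  expect_setequal(ppi_neighbors(tri, "b"), c("a", "c"))
})

test_that("overlap statistics behave at the identical and disjoint limits", {
  # identical ranked neighbourhoods share exactly k genes at every k
  ranked <- structure(list(
    queries = c("q1", "q2"),
    scores = list(q1 = data.frame(gene = paste0("g", 1:10)),
                  q2 = data.frame(gene = paste0("h", 1:10)))),
    class = "iknn")
  self <- neighborhood_overlap(ranked, ranked, k = c(2, 5, 10))
  expect_true(all(self$counts[, "2"] == 2))
  expect_true(all(self$counts[, "5"] == 5))
  expect_true(all(self$counts[, "10"] == 10))

  a <- list(q1 = paste0("g", 1:10), q2 = paste0("h", 1:10))
  b <- list(q1 = paste0("x", 1:10), q2 = paste0("y", 1:10))
  none <- neighborhood_overlap(a, b, k = 5)
  expect_true(all(none$counts == 0))
  expect_equal(none$summary$t_stat, 0)
  expect_equal(none$summary$p_value, 1)
})

test_that("random neighbourhood overlap matches the k^2/N expectation", {
  set.seed(11)
  pool <- sprintf("g%03d", 1:100)
  k <- 10
  qs <- sprintf("q%02d", 1:60)
  a <- setNames(lapply(qs, function(q) sample(pool, k)), qs)
  b <- setNames(lapply(qs, function(q) sample(pool, k)), qs)
  ov <- neighborhood_overlap(a, b, k = k)
  # E|intersection| = k^2 / N = 1; SE ~ sqrt(var/60) < 0.2
  expect_lt(abs(ov$summary$mean_shared - 1), 0.5)
})

test_that("the fitted network export carries fused weights", {
  ds <- simulate_dataset(sim_config(n_genes = 50, n_modules = 1,
                                    module_size = 4, seed = 30))
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 4)
  net <- as_network(fit)
  expect_s3_class(net, "gene_network")
  expect_equal(nrow(net), 4L)
  expect_true(all(net$weight >= 0 & net$weight <= 1))
})
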