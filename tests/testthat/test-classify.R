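# Biosignature encodings, LOOCV linear-SVM evaluation, ROC/AUC and the
# model-family comparison.

make_cohort <- function(seed = 1, delta = 2) {
  simulate_dataset(sim_config(n_genes = 80, n_modules = 2, module_size = 6,
                              delta = delta, seed = seed))
}

test_that("integrated-neighbourhood encoding yields one feature per query", {
  ds <- simulate_dataset(sim_config(n_genes = 150, n_modules = 6,
                                    module_size = 5, seed = 41))
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 5)
  sig <- biosignature(fit, "integrated_neighborhood")
  feats <- build_features(sig, ds$expr)
  expect_equal(ncol(feats), 6L)
  expect_equal(colnames(feats), ds$config$queries)
  expect_equal(nrow(feats), ncol(ds$expr$values))
})

test_that("a query with an empty neighbourhood contributes its own profile", {
  ds <- make_cohort(seed = 42)
  q <- ds$config$queries[1]
  sig <- biosignature(q, "integrated_neighborhood")
  feats <- build_features(sig, ds$expr)
  std <- standardize_expression(ds$expr)
  expect_equal(unname(feats[, 1]), unname(std$values[q, ]))
})

test_that("neighbourhood features are invariant to member order", {
  ds <- make_cohort(seed = 43)
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 5)
  nbs <- lapply(fit$neighborhoods, `[[`, "gene")
  sig1 <- biosignature(nbs, "integrated_neighborhood")
  sig2 <- biosignature(lapply(nbs, rev), "integrated_neighborhood")
  expect_equal(build_features(sig1, ds$expr), build_features(sig2, ds$expr))
})

test_that("individual-gene encoding spans the distinct signature genes", {
  ds <- make_cohort(seed = 44)
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 4)
  sig <- biosignature(fit, "individual_gene")
  feats <- build_features(sig, ds$expr)
  genes <- unique(c(fit$queries, unlist(lapply(fit$neighborhoods, `[[`, "gene"))))
  expect_setequal(colnames(feats), genes)
})

test_that("missing signature genes are dropped; empty signatures error", {
  ds <- make_cohort(seed = 45)
  sig <- biosignature(c(ds$config$queries[1], "ABSENT"), "individual_gene")
  expect_warning(feats <- build_features(sig, ds$expr), "absent")
  expect_equal(ncol(feats), 1L)
  bad <- biosignature("ABSENT", "individual_gene")
  expect_error(suppressWarnings(build_features(bad, ds$expr)),
               "zero features")
})

test_that("AUC equals exhaustive pair enumeration, with ties", {
  set.seed(5)
  labels <- rep(c("treated", "untreated"), each = 6)
  for (i in 1:25) {
    scores <- sample(round(rnorm(12), 1))  # rounding forces ties
    ev <- roc_auc(scores, labels)
    expect_equal(ev$auc, oracle_auc_pairs(scores, labels, "treated"),
                 tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(3, 2, 1, 0), c("treated", "treated",
                                        "untreated", "untreated"))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 2, 3), c("treated", "treated",
                                        "untreated", "untreated"))$auc, 0)
  expect_error(roc_auc(1:3, rep("treated", 3)), "both classes")
})

test_that("threshold-sweep trapezoid area equals the pairwise AUC", {
  set.seed(6)
  labels <- rep(c("treated", "untreated"), each = 8)
  for (i in 1:25) {
    scores <- sample(round(rnorm(16), 1))
    ev <- roc_auc(scores, labels)
    expect_equal(oracle_trapezoid(ev$roc), ev$auc, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  labels <- rep(c("treated", "untreated"), each = 10)
  for (i in 1:10) {
    scores <- rnorm(20)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("untreated", "treated"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("LOOCV separates well-separated classes perfectly", {
  set.seed(8)
  X <- matrix(rnorm(12 * 3, sd = 0.3), 12)
  X[1:6, ] <- X[1:6, ] + 4
  labels <- rep(c("treated", "untreated"), each = 6)
  ev <- svm_loocv(X, labels)
  expect_equal(ev$auc, 1)
  expect_equal(length(ev$scores), 12L)
  expect_equal(ev$model_config$cost, 100)
})

test_that("an all-constant feature scores AUC 0.5 under tie handling", {
  labels <- rep(c("treated", "untreated"), each = 4)
  ev <- svm_loocv(matrix(1, 8, 1), labels)
  expect_equal(ev$auc, 0.5)
})

test_that("held-out scores are invariant to the ordering of other samples", {
  set.seed(9)
  X <- matrix(rnorm(12 * 4), 12, dimnames = list(paste0("s", 1:12), NULL))
  labels <- setNames(rep(c("treated", "untreated"), each = 6), rownames(X))
  ev1 <- svm_loocv(X, labels)
  perm <- sample(12)
  ev2 <- svm_loocv(X[perm, ], labels[perm])
  # libsvm solves to a numerical tolerance, so invariance is approximate
  expect_equal(ev2$scores[names(ev1$scores)], ev1$scores, tolerance = 1e-3)
})

test_that("LOOCV refuses degenerate class layouts", {
  X <- matrix(rnorm(12), 6)
  expect_error(svm_loocv(X, c("a", "a", "a", "a", "a", "b")),
               "at least 2 samples per class")
  expect_error(svm_loocv(X, rep("a", 6)), "two classes")
})

test_that("model comparison is deterministic and favours planted signal", {
  ds <- make_cohort(seed = 46, delta = 2)
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 6)
  sig <- biosignature(fit, "integrated_neighborhood", name = "Q+6NN")
  cm1 <- compare_models(list(sig), ds$expr)
  cm2 <- compare_models(list(sig), ds$expr)
  expect_identical(cm1$auc, cm2$auc)
})

test_that("planted neighbourhoods beat shuffled controls, paired", {
  # paired replicates at a modest effect size, so that diluting the query
  # feature with unrelated genes costs measurable performance
  deltas <- vapply(1:10, function(r) {
    ds <- simulate_dataset(sim_config(n_genes = 80, n_modules = 2,
                                      module_size = 6, delta = 1,
                                      seed = 400 + r))
    fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 6)
    sig <- biosignature(fit, "integrated_neighborhood", name = "planted")
    planted <- unlist(lapply(ds$config$modules, function(m)
      c(m$query, m$members)))
    noise <- setdiff(rownames(ds$expr$values), planted)
    set.seed(r)
    shuffled <- setNames(lapply(fit$queries, function(q) sample(noise, 6)),
                         fit$queries)
    ctrl <- biosignature(shuffled, "integrated_neighborhood", name = "ctrl")
    cm <- compare_models(list(sig, ctrl), ds$expr)
    cm$auc[cm$name == "planted"] - cm$auc[cm$name == "ctrl"]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("the k sweep emits one row per requested k", {
  ds <- make_cohort(seed = 47)
  fit <- iknn(ds$expr, ds$model, ds$config$queries, k = 20)
  curve <- auc_by_k(fit, ds$expr, k = 1:20)
  expect_equal(nrow(curve), 20L)
  expect_equal(curve$k, 1:20)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
})
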