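# Biosignature assembly and treated-vs-untreated classification: two input
# representations (individual gene / integrated gene neighbourhood), linear
# max-margin models at complexity constant 100, leave-one-out
# cross-validation, and ROC/AUC scoring of the pooled held-out decision
# values.

#' Assemble a biosignature
#'
#' A biosignature is a set of query genes plus (possibly empty) retrieved
#' neighbourhoods, together with the input representation under which it is
#' presented to the classifier:
#' * `"integrated_neighborhood"` — one feature per query, the mean
#'   standardized expression of the query and its neighbours;
#' * `"individual_gene"` — one feature per distinct gene in the signature.
#'
#' @param x Either an [iknn] fit (queries and fitted neighbourhoods), a
#'   character vector of query genes (query-only signature, e.g. the
#'   expert-query or differential-expression models), or a named list
#'   mapping each query to a character vector of neighbours (e.g. PPI
#'   partner sets).
#' @param representation Input representation (see above).
#' @param name Signature name used in comparison tables.
#' @return An object of class `biosignature`.
#' @export
biosignature <- function(x,
                         representation = c("integrated_neighborhood",
                                            "individual_gene"),
                         name = NULL) {
  representation <- match.arg(representation)
  if (inherits(x, "iknn")) {
    queries <- x$queries
    nbs <- lapply(x$neighborhoods, function(nb) nb$gene)
    if (is.null(name)) name <- sprintf("%dNN", x$k)
  } else if (is.character(x)) {
    queries <- unique(x)
    nbs <- stats::setNames(rep(list(character(0)), length(queries)), queries)
    if (is.null(name)) name <- "queries"
  } else if (is.list(x) && !is.null(names(x))) {
    queries <- names(x)
    nbs <- lapply(x, as.character)
    if (is.null(name)) name <- "sets"
  } else {
    stop("`x` must be an iknn fit, a character vector, or a named list")
  }
  structure(list(name = name, queries = queries, neighborhoods = nbs,
                 representation = representation),
            class = "biosignature")
}

#' @export
print.biosignature <- function(x, ...) {
  cat(sprintf("biosignature '%s' (%s): %d queries, %d genes total\n",
              x$name, x$representation, length(x$queries),
              length(unique(c(x$queries, unlist(x$neighborhoods))))))
  invisible(x)
}

#' Encode a biosignature as a classifier feature matrix
#'
#' Builds the samples-by-features design matrix from standardized
#' expression. Under the integrated-neighbourhood representation each query
#' contributes one feature: the per-sample mean of the query's and its
#' neighbours' standardized expression (a query with an empty neighbourhood
#' contributes its own profile). Under the individual-gene representation
#' every distinct signature gene contributes its own standardized profile.
#' Genes absent from the matrix are dropped with a warning; a signature
#' resolving to zero features is an error.
#'
#' @param signature A [biosignature].
#' @param expr An [expression_data] object (standardized on the fly if
#'   needed).
#' @return Numeric matrix, samples in rows, features in columns.
#' @export
build_features <- function(signature, expr) {
  stopifnot(inherits(signature, "biosignature"),
            inherits(expr, "expression_data"))
  expr <- standardize_expression(expr)
  v <- expr$values
  missing <- setdiff(unique(c(signature$queries,
                              unlist(signature$neighborhoods))),
                     rownames(v))
  if (length(missing)) {
    warning(sprintf("%d signature gene(s) absent from the expression matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  if (signature$representation == "individual_gene") {
    genes <- intersect(unique(c(signature$queries,
                                unlist(signature$neighborhoods))),
                       rownames(v))
    if (!length(genes)) stop("signature resolves to zero features")
    feats <- t(v[genes, , drop = FALSE])
  } else {
    cols <- lapply(signature$queries, function(q) {
      members <- intersect(unique(c(q, signature$neighborhoods[[q]])),
                           rownames(v))
      if (!length(members)) return(NULL)
      colMeans(v[members, , drop = FALSE])
    })
    keep <- !vapply(cols, is.null, TRUE)
    if (!any(keep)) stop("signature resolves to zero features")
    feats <- do.call(cbind, cols[keep])
    colnames(feats) <- signature$queries[keep]
  }
  rownames(feats) <- colnames(v)
  feats
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the Mann-Whitney pairwise concordance
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)` — computed via midranks —
#' and the ROC points come from sweeping a threshold across the observed
#' scores (positive called when score >= threshold). The two routes agree:
#' the trapezoidal area under the returned points equals the pairwise AUC.
#'
#' @param scores Numeric decision scores, higher favouring the positive
#'   class.
#' @param labels Factor or character vector of class labels.
#' @param positive The positive-class label; defaults to `"treated"` when
#'   present, otherwise the last factor level.
#' @return List with `auc`, `roc` (data frame of `threshold`, `fpr`,
#'   `tpr`, including the (0,0) and (1,1) endpoints) and `positive`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.factor(labels)
  positive <- .positive_class(labels, positive)
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5 concordance
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(is_pos & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!is_pos & scores >= t) / n_neg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc, positive = positive)
}

.positive_class <- function(labels, positive = NULL) {
  lev <- levels(as.factor(labels))
  if (is.null(positive)) {
    positive <- if ("treated" %in% lev) "treated" else lev[length(lev)]
  }
  if (!(positive %in% lev)) stop("positive class '", positive, "' not in labels")
  positive
}

#' Leave-one-out cross-validated linear SVM evaluation
#'
#' For every sample in turn, a linear support vector machine (libsvm
#' C-classification, linear kernel, complexity constant `cost = 100`, no
#' feature rescaling) is trained on the remaining samples and the held-out
#' sample's projection onto the unit normal of the separating hyperplane
#' is recorded as its decision score. The fold intercept is omitted
#' because every leave-one-out training fold is class-imbalanced by one
#' sample and the intercept absorbs that imbalance, biasing pooled scores
#' downward for the held-out class; the normal projection is exchangeable
#' under label permutation, so the pooled null AUC is centred at 0.5. The
#' pooled held-out scores, oriented so that larger means more `positive`,
#' are summarized by a ROC curve and its AUC.
#'
#' @param features Samples-by-features numeric matrix (see
#'   [build_features()]).
#' @param labels Per-sample class labels (two classes, at least 2 samples
#'   each).
#' @param cost SVM complexity constant C.
#' @param positive Positive-class label (see [roc_auc()]).
#' @return An object of class `classifier_eval`: list with `scores` (named
#'   held-out decision values), `labels`, `auc`, `roc`, `positive` and
#'   `model_config`.
#' @export
svm_loocv <- function(features, labels, cost = 100, positive = NULL) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) stop("one label per sample required")
  if (nlevels(droplevels(labels)) != 2L) stop("exactly two classes required")
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  positive <- .positive_class(labels, positive)

  n <- nrow(features)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    scores[i] <- .svm_decision(features[-i, , drop = FALSE], labels[-i],
                               features[i, , drop = FALSE], cost, positive)
  }
  names(scores) <- rownames(features)
  ev <- roc_auc(scores, labels, positive)
  structure(
    list(scores = scores, labels = labels, auc = ev$auc, roc = ev$roc,
         positive = positive,
         model_config = list(model = "svm", kernel = "linear",
                             cost = cost, backend = "libsvm (e1071)")),
    class = "classifier_eval"
  )
}

# Decision score of `newdata` under a linear SVM trained on (x, y):
# the projection onto the unit normal of the separating hyperplane,
# oriented so positive values favour the `positive` class. The fold's
# intercept is deliberately omitted: in pooled LOOCV each training fold is
# class-imbalanced by construction, and the intercept absorbs that
# imbalance, biasing pooled scores against the held-out sample's class;
# the normal projection (the signed distance up to the fold's constant
# offset) is exchangeable under label permutation. A degenerate training
# set (e.g. all-constant features) yields score 0.
.svm_decision <- function(x, y, newdata, cost, positive) {
  fit <- tryCatch(
    e1071::svm(x = x, y = droplevels(y), kernel = "linear", cost = cost,
               scale = FALSE, type = "C-classification"),
    error = function(e) NULL
  )
  if (is.null(fit)) return(0)
  w <- crossprod(fit$coefs, fit$SV)  # decision value is w.x - rho
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(0)
  score <- sum(w * newdata) / nw
  # libsvm orders classes by order of appearance in the training data, so
  # read the orientation off the decision-value column name
  pred <- stats::predict(fit, newdata, decision.values = TRUE)
  first <- strsplit(colnames(attr(pred, "decision.values"))[1L],
                    "/", fixed = TRUE)[[1L]][1L]
  if (first == positive) score else -score
}

#' @export
print.classifier_eval <- function(x, digits = 3, ...) {
  cat(sprintf("LOOCV %s (%s kernel, C = %g): AUC = %s over %d samples\n",
              toupper(x$model_config$model), x$model_config$kernel,
              x$model_config$cost, format(round(x$auc, digits)),
              length(x$scores)))
  invisible(x)
}

#' @export
plot.classifier_eval <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("LOOCV ROC (AUC = %.2f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Evaluate a biosignature as a treated-vs-untreated classifier
#'
#' Convenience wrapper: encodes the signature with [build_features()] using
#' the labels stored on `expr` and evaluates it with [svm_loocv()].
#'
#' @param signature A [biosignature].
#' @param expr A labelled [expression_data] object.
#' @inheritParams svm_loocv
#' @return A `classifier_eval`.
#' @export
evaluate_signature <- function(signature, expr, cost = 100, positive = NULL) {
  stopifnot(inherits(expr, "expression_data"))
  if (is.null(expr$labels)) stop("`expr` carries no condition labels")
  feats <- build_features(signature, expr)
  svm_loocv(feats, expr$labels, cost = cost, positive = positive)
}

#' Compare a family of biosignature models
#'
#' Evaluates each signature under LOOCV and returns the comparison table
#' (name, representation, feature count, AUC) ranked by AUC — the
#' query-only vs query+neighbourhood vs PPI-baseline model family
#' comparison.
#'
#' @param signatures List of [biosignature] objects.
#' @param expr A labelled [expression_data] object.
#' @inheritParams svm_loocv
#' @return Data frame of class `model_comparison`, ordered by decreasing
#'   AUC, with attribute `evaluations` holding the full `classifier_eval`
#'   objects.
#' @export
compare_models <- function(signatures, expr, cost = 100, positive = NULL) {
  stopifnot(is.list(signatures), length(signatures) > 0)
  evs <- lapply(signatures, function(s) {
    feats <- build_features(s, expr)
    list(sig = s, n_features = ncol(feats),
         eval = svm_loocv(feats, expr$labels, cost = cost, positive = positive))
  })
  out <- do.call(rbind, lapply(evs, function(e) {
    data.frame(name = e$sig$name, representation = e$sig$representation,
               n_features = e$n_features, auc = e$eval$auc,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$auc, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evaluations") <- stats::setNames(lapply(evs, `[[`, "eval"),
                                              vapply(evs, function(e) e$sig$name, ""))
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  attr(y, "evaluations") <- NULL
  y$auc <- round(y$auc, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' AUC as a function of neighbourhood size k
#'
#' Re-cuts the fitted ranking of an [iknn] object at each `k` (the
#' neighbourhoods are prefixes of one full sort, so no re-scoring is
#' needed), builds the corresponding signature, and records the LOOCV AUC —
#' the classification-performance-versus-k sweep.
#'
#' @param fit An [iknn] fit.
#' @param expr A labelled [expression_data] object.
#' @param k Integer vector of neighbourhood sizes (default `1:20`).
#' @param representation Signature representation (default integrated
#'   neighbourhood).
#' @inheritParams svm_loocv
#' @return Data frame of class `auc_curve` with columns `k`, `n_features`,
#'   `auc`.
#' @export
auc_by_k <- function(fit, expr, k = 1:20,
                     representation = c("integrated_neighborhood",
                                        "individual_gene"),
                     cost = 100, positive = NULL) {
  stopifnot(inherits(fit, "iknn"))
  representation <- match.arg(representation)
  rows <- lapply(k, function(kk) {
    nbs <- lapply(fit$scores, function(s) utils::head(s$gene, kk))
    sig <- biosignature(nbs, representation = representation,
                        name = sprintf("%dNN", kk))
    feats <- build_features(sig, expr)
    ev <- svm_loocv(feats, expr$labels, cost = cost, positive = positive)
    data.frame(k = kk, n_features = ncol(feats), auc = ev$auc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("auc_curve", "data.frame")
  out
}

#' @export
plot.auc_curve <- function(x, ...) {
  plot(x$k, x$auc, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "neighbourhood size k", ylab = "LOOCV AUC",
       main = "Classification performance vs k", ...)
  abline(h = 0.5, lty = 3, col = "grey60")
  invisible(x)
}
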