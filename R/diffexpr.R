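# SAM-style differential expression for data-driven query selection: a
# moderated standardized mean difference d = (mean_t - mean_c) / (s + s0),
# permutation-based false discovery rate estimation, and a joint
# fold-change / FDR selection rule.

#' Moderated difference statistic for one gene
#'
#' `d = (mean(treated) - mean(control)) / (s + s0)` where `s` is the pooled
#' standard error of the mean difference,
#' `s = sqrt(((1/n_t + 1/n_c) * (SS_t + SS_c)) / (n_t + n_c - 2))`, and
#' `s0` is the exchangeability ("fudge") constant that stabilizes genes
#' with near-zero variance. `d` is antisymmetric in its two groups, and any
#' `s0 > 0` strictly shrinks `|d|` on non-degenerate input.
#'
#' @param treated,control Numeric vectors, each of length >= 2.
#' @param s0 Non-negative fudge constant.
#' @return The d statistic; `NA_real_` when both groups have zero variance
#'   and `s0 = 0` (undefined).
#' @export
d_statistic <- function(treated, control, s0 = 0) {
  stopifnot(is.numeric(treated), is.numeric(control),
            length(treated) >= 2L, length(control) >= 2L,
            is.numeric(s0), length(s0) == 1L, s0 >= 0)
  n1 <- length(treated); n2 <- length(control)
  ss <- sum((treated - mean(treated))^2) + sum((control - mean(control))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (s + s0 == 0) return(NA_real_)
  (mean(treated) - mean(control)) / (s + s0)
}

# Vectorized d statistics for all rows of x given treated-column indices.
.d_stat_matrix <- function(x, idx_t, s0) {
  idx_c <- setdiff(seq_len(ncol(x)), idx_t)
  n1 <- length(idx_t); n2 <- length(idx_c)
  xt <- x[, idx_t, drop = FALSE]; xc <- x[, idx_c, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  ss <- rowSums((xt - mt)^2) + rowSums((xc - mc)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  d <- (mt - mc) / (s + s0)
  d[s + s0 == 0] <- NA_real_
  list(d = d, s = s, mean_diff = mt - mc)
}

# Default fudge constant: the median of the per-gene pooled standard
# errors (a simplified stand-in for the original percentile search).
.default_s0 <- function(s) stats::median(s, na.rm = TRUE)

#' Permutation-based FDR (q-values) for the d statistic
#'
#' Estimates, for each gene, the SAM-style false discovery rate of calling
#' every gene at least as extreme: q(g) = (median over label permutations
#' of the number of null `|d*|` values exceeding `|d(g)|`) divided by the
#' observed number of genes with `|d| >= |d(g)|`, clipped to `[0, 1]` and
#' made monotone non-increasing in `|d|` by a step-up pass. When the
#' requested number of permutations covers all distinct treated/control
#' assignments the null is enumerated exhaustively; otherwise label
#' shuffles are sampled under `seed`.
#'
#' @param x Genes-by-samples numeric matrix.
#' @param labels Per-sample two-class labels (character or factor).
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param s0 Fudge constant; `NULL` uses the median per-gene pooled
#'   standard error.
#' @param seed Integer seed for sampled permutations (ignored when the
#'   null is enumerated exhaustively).
#' @param positive Label of the treated class (see [roc_auc()]).
#' @return Numeric vector of q-values, one per row of `x`.
#' @export
permutation_fdr <- function(x, labels, n_perm = 1000, s0 = NULL, seed = NULL,
                            positive = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(x), nlevels(droplevels(labels)) == 2L)
  positive <- .positive_class(labels, positive)
  idx_t <- which(labels == positive)
  n <- ncol(x)

  obs <- .d_stat_matrix(x, idx_t, s0 = 0)
  if (is.null(s0)) s0 <- .default_s0(obs$s)
  d_obs <- abs(.d_stat_matrix(x, idx_t, s0)$d)

  n_distinct <- choose(n, length(idx_t))
  if (n_perm >= n_distinct) {
    perms <- utils::combn(n, length(idx_t), simplify = FALSE)
  } else {
    perms <- .with_seed(seed, replicate(n_perm,
      sample.int(n, length(idx_t)), simplify = FALSE))
  }

  ok <- which(!is.na(d_obs))
  ord <- ok[order(d_obs[ok])]  # ascending |d|
  d_sorted <- d_obs[ord]
  # exceed[p, r]: how many null |d*| in permutation p are >= the r-th
  # smallest observed |d|
  exceed <- matrix(0L, nrow = length(perms), ncol = length(ord))
  for (p in seq_along(perms)) {
    d_null <- sort(abs(.d_stat_matrix(x, perms[[p]], s0)$d), na.last = NA)
    # count of null values >= threshold, via position in the sorted nulls
    pos <- findInterval(d_sorted, d_null, left.open = TRUE)
    exceed[p, ] <- length(d_null) - pos
  }
  med_false <- apply(exceed, 2L, stats::median)
  # genes with equal |d| are called together
  n_called <- vapply(d_sorted, function(v) sum(d_obs >= v, na.rm = TRUE),
                     numeric(1))
  q_sorted <- pmin(1, pmax(0, med_false / pmax(n_called, 1)))
  # step-up monotonization: each gene takes the minimum raw q among genes
  # with smaller-or-equal |d|, making q non-increasing in |d|
  q_sorted <- cummin(q_sorted)
  q <- rep(NA_real_, nrow(x))
  q[ord] <- q_sorted
  q
}

#' SAM-style differential expression analysis
#'
#' Computes per-gene moderated d statistics, anti-logged fold-changes
#' between group means (`fc = base^(mean_t - mean_c)`, for log-scale
#' intensities), and permutation-based q-values.
#'
#' @param expr A labelled, unstandardized [expression_data] object of
#'   log-scale intensities.
#' @inheritParams permutation_fdr
#' @param base Logarithm base of the intensities, used to anti-log the
#'   fold-change (default 2).
#' @return Data frame of class `de_results` with columns `gene_id`,
#'   `d_stat`, `fold_change`, `q_value`, in input gene order; the `s0`
#'   used is recorded as an attribute.
#' @export
sam_de <- function(expr, n_perm = 1000, s0 = NULL, seed = NULL,
                   positive = NULL, base = 2) {
  stopifnot(inherits(expr, "expression_data"))
  if (is.null(expr$labels)) stop("`expr` carries no condition labels")
  x <- expr$values
  labels <- expr$labels
  positive <- .positive_class(labels, positive)
  idx_t <- which(labels == positive)

  raw <- .d_stat_matrix(x, idx_t, s0 = 0)
  if (is.null(s0)) s0 <- .default_s0(raw$s)
  mod <- .d_stat_matrix(x, idx_t, s0)
  q <- permutation_fdr(x, labels, n_perm = n_perm, s0 = s0, seed = seed,
                       positive = positive)
  out <- data.frame(gene_id = rownames(x), d_stat = unname(mod$d),
                    fold_change = unname(base^mod$mean_diff),
                    q_value = unname(q), stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  class(out) <- c("de_results", "data.frame")
  out
}

#' Select data-driven query genes
#'
#' The joint rule used to pick the most highly differentially expressed
#' genes as queries: anti-logged fold-change at least `fold_change_min` (or
#' at most its reciprocal, for down-regulation) and q-value at most
#' `fdr_max`; the selection is ordered by decreasing `|d|`.
#'
#' @param de A `de_results` data frame from [sam_de()].
#' @param fold_change_min Fold-change threshold (default 1.7).
#' @param fdr_max FDR threshold (default 0.01).
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
select_queries <- function(de, fold_change_min = 1.7, fdr_max = 0.01) {
  stopifnot(inherits(de, "de_results") ||
              all(c("gene_id", "d_stat", "fold_change", "q_value") %in% names(de)))
  stopifnot(fold_change_min >= 1, fdr_max >= 0)
  keep <- (de$fold_change >= fold_change_min |
             de$fold_change <= 1 / fold_change_min) &
    !is.na(de$q_value) & de$q_value <= fdr_max
  sel <- de[which(keep), , drop = FALSE]
  if (!nrow(sel)) {
    warning("no gene passes fold-change >= ", fold_change_min,
            " and FDR <= ", fdr_max)
    return(character(0))
  }
  sel$gene_id[order(-abs(sel$d_stat))]
}
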