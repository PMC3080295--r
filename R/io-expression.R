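#' Expression data container
#'
#' A lightweight container for a genes-by-samples matrix of log-scale
#' intensities with an optional binary condition label per sample. This is
#' the object every downstream step of the package consumes: the
#' co-expression component of the integrated kNN score, the SAM-style
#' differential expression statistic, and the classifier feature builders.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). No missing values are allowed.
#' @param labels Optional per-sample condition, either a character/factor
#'   vector in column order or a named vector keyed by sample id. When both
#'   conditions `"treated"` and `"untreated"` occur, the factor is ordered
#'   `untreated < treated` so that `"treated"` is the positive class.
#' @param standardized Logical; `TRUE` when each row has already been scaled
#'   to mean 0, sd 1.
#'
#' @return An object of class `expression_data`: a list with elements
#'   `values`, `labels` (factor or `NULL`) and `standardized`.
#' @seealso [read_expression()], [standardize_expression()]
#' @export
expression_data <- function(values, labels = NULL, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene ids)")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample ids)")
  }
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (!is.null(labels)) {
    labels <- .resolve_labels(labels, colnames(values))
  }
  structure(
    list(values = values, labels = labels,
         standardized = isTRUE(standardized)),
    class = "expression_data"
  )
}

.resolve_labels <- function(labels, sample_ids) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("`labels` must be named by sample id or match the number of samples")
  }
  lev <- unique(labels)
  if (length(lev) > 2L) {
    stop("labels must define at most two conditions, got: ",
         paste(lev, collapse = ", "))
  }
  if (setequal(lev, c("treated", "untreated"))) {
    lev <- c("untreated", "treated")
  } else {
    lev <- sort(lev)
  }
  factor(labels, levels = lev)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene ids (e.g. replicate probes mapped to one symbol) are
#' averaged; exact duplicates collapse silently apart from a message, while
#' rows that disagree by more than `conflict_tol` are averaged with a
#' warning naming the gene. Non-numeric cells are an error that names the
#' offending gene and sample. Missing values are rejected unless
#' `impute = TRUE`, in which case they are replaced by the gene's mean.
#'
#' @param path Path to the TSV file.
#' @param labels Optional sample condition labels: a named vector keyed by
#'   sample id, a vector in column order, or the path to a two-column TSV
#'   (sample id, condition).
#' @param impute Impute missing cells with the per-gene mean instead of
#'   rejecting the file.
#' @param conflict_tol Maximum absolute disagreement between duplicated rows
#'   before the collapse is reported as a conflict.
#' @return An [expression_data] object (not yet standardized).
#' @export
read_expression <- function(path, labels = NULL, impute = FALSE,
                            conflict_tol = 1e-9) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene id column and at least one sample")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) & !(cell %in% c("", "NA", "na", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' for gene '%s' (row %d), sample '%s' (column %d)",
                   cell[bad[1L]], gene_ids[bad[1L]], bad[1L],
                   sample_ids[j], j + 1L))
    }
    num[, j] <- v
  }
  rownames(num) <- make.unique(gene_ids)

  # collapse duplicated gene ids by averaging
  if (anyDuplicated(gene_ids)) {
    grp <- split(seq_along(gene_ids), gene_ids)
    dup <- names(grp)[vapply(grp, length, 1L) > 1L]
    collapsed <- matrix(NA_real_, nrow = length(grp), ncol = ncol(num),
                        dimnames = list(names(grp), sample_ids))
    conflicts <- character(0)
    for (g in names(grp)) {
      block <- num[grp[[g]], , drop = FALSE]
      if (nrow(block) > 1L) {
        spread <- apply(block, 2L, function(col) diff(range(col, na.rm = TRUE)))
        if (any(is.finite(spread) & spread > conflict_tol)) {
          conflicts <- c(conflicts, g)
        }
      }
      collapsed[g, ] <- colMeans(block)
    }
    if (length(conflicts)) {
      warning("conflicting duplicate rows averaged for gene(s): ",
              paste(conflicts, collapse = ", "))
    }
    message(sprintf("collapsed %d duplicated gene id(s) by averaging", length(dup)))
    # restore first-occurrence order
    collapsed <- collapsed[unique(gene_ids), , drop = FALSE]
    num <- collapsed
  }

  if (anyNA(num)) {
    if (!impute) {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value for gene '%s', sample '%s'; use impute = TRUE for per-gene mean imputation",
                   rownames(num)[bad[1L]], colnames(num)[bad[2L]]))
    }
    for (i in which(rowSums(is.na(num)) > 0L)) {
      row <- num[i, ]
      if (all(is.na(row))) stop("gene '", rownames(num)[i], "' has no observed values")
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      num[i, ] <- row
    }
  }

  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) &&
      file.exists(labels)) {
    lab <- utils::read.delim(labels, header = FALSE, sep = "\t", quote = "",
                             colClasses = "character")
    labels <- stats::setNames(lab[[2L]], lab[[1L]])
  }
  expression_data(num, labels = labels)
}

#' Standardize expression rows to mean 0, sd 1
#'
#' Each gene's profile across samples is centred and scaled by its sample
#' standard deviation, the standard pre-processing applied before
#' co-expression and classification. Rows with zero variance cannot be
#' standardized and are excluded with a warning; they carry no correlation
#' signal and would otherwise contaminate the candidate pool.
#'
#' @param x An [expression_data] object.
#' @return An [expression_data] object with `standardized = TRUE`. Already
#'   standardized input is returned unchanged.
#' @export
standardize_expression <- function(x) {
  stopifnot(inherits(x, "expression_data"))
  if (isTRUE(x$standardized)) return(x)
  v <- x$values
  s <- .row_sd(v)
  flat <- !is.finite(s) | s == 0
  if (any(flat)) {
    warning(sprintf("excluded %d zero-variance gene row(s): %s", sum(flat),
                    paste(utils::head(rownames(v)[flat], 5L), collapse = ", ")))
    v <- v[!flat, , drop = FALSE]
    s <- s[!flat]
  }
  if (!nrow(v)) stop("no gene rows left after removing zero-variance rows")
  v <- (v - rowMeans(v)) / s
  expression_data(v, labels = x$labels, standardized = TRUE)
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("expression_data: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_data <- function(x) dim(x$values)

#' Write an expression matrix (and optional labels) as TSV
#'
#' Inverse of [read_expression()]: the first column holds gene ids, the
#' header row sample ids. When `labels_path` is given the sample conditions
#' are written as a two-column TSV alongside.
#'
#' @param x An [expression_data] object.
#' @param path Output TSV path.
#' @param labels_path Optional output path for the label table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "expression_data"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(x$labels)) stop("no labels to write")
    utils::write.table(
      data.frame(sample = colnames(x$values), condition = as.character(x$labels)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}
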