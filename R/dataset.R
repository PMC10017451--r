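#' Labeled expression dataset
#'
#' The central container of the package: a dense cells x genes matrix of
#' non-negative expression values (log-normalized scale) together with unique
#' cell and gene identifiers and one class label per cell. Labels are stored
#' as a factor whose levels define the class set used by every downstream
#' stage (ranking, cross-validation, metrics).
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(values)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `rownames(values)`).
#' @param labels per-cell class labels (factor or character), length
#'   `nrow(values)`.
#' @return an object of class `expr_dataset` with elements `values`
#'   (dimnamed matrix), `gene_ids`, `cell_ids`, `labels` (factor).
#' @export
expr_dataset <- function(values, gene_ids = colnames(values),
                         cell_ids = rownames(values), labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stopf("gene identifiers are required")
  if (is.null(cell_ids)) stopf("cell identifiers are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values))
    stopf("%d gene ids for %d matrix columns", length(gene_ids), ncol(values))
  if (length(cell_ids) != nrow(values))
    stopf("%d cell ids for %d matrix rows", length(cell_ids), nrow(values))
  if (anyDuplicated(gene_ids)) stopf("gene ids must be unique")
  if (anyDuplicated(cell_ids)) stopf("cell ids must be unique")
  if (length(labels) != nrow(values))
    stopf("%d labels for %d cells", length(labels), nrow(values))
  if (anyNA(values)) stopf("expression values must not contain missing values")
  if (anyNA(labels)) stopf("labels must not contain missing values")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = labels),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

n_classes <- function(ds) nlevels(ds$labels)

#' Gene ranking
#'
#' An ordered gene list produced by one feature-ranking algorithm, together
#' with the per-gene importance score that induced the order. The order may
#' cover all genes of a dataset or a declared top-N prefix.
#'
#' @param method one of `"mrmr"`, `"mcfs"`, `"lasso"`, `"gbdt_split"`,
#'   `"pfi"`.
#' @param ordered_genes character vector of gene ids, most important first.
#' @param scores numeric vector aligned with `ordered_genes`.
#' @param seed integer seed used by the ranker, or `NA` for deterministic
#'   methods.
#' @param extra optional data.frame of auxiliary per-gene columns (e.g. the
#'   total split gain reported alongside split counts), aligned with
#'   `ordered_genes`.
#' @return an object of class `gene_ranking`.
#' @export
gene_ranking <- function(method, ordered_genes, scores, seed = NA_integer_,
                         extra = NULL) {
  method <- match.arg(method, c("mrmr", "mcfs", "lasso", "gbdt_split", "pfi"))
  ordered_genes <- as.character(ordered_genes)
  if (anyDuplicated(ordered_genes)) stopf("ranking contains duplicate genes")
  if (length(scores) != length(ordered_genes))
    stopf("scores and ordered_genes lengths differ")
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != length(ordered_genes))
      stopf("extra columns must align with ordered_genes")
  }
  structure(
    list(method = method, ordered_genes = ordered_genes,
         scores = as.numeric(scores), seed = seed, extra = extra),
    class = "gene_ranking"
  )
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking> method=%s, %d genes\n", x$method,
              length(x$ordered_genes)))
  k <- min(5L, length(x$ordered_genes))
  cat("top:", paste(sprintf("%s (%.4g)", x$ordered_genes[seq_len(k)],
                            x$scores[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}
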