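# Readers/writers for the plain-text formats the pipeline touches:
# MatrixMarket triplets with gene/cell sidecars (CellRanger-style), dense
# TSV, label TSV and ranking TSV. All writers emit UTF-8 with LF endings and
# are byte-deterministic for identical inputs.

read_tsv_col <- function(path) {
  readLines(path, encoding = "UTF-8")
}

#' Read a labeled expression dataset
#'
#' @param matrix_path path to the matrix: a `.mtx` MatrixMarket triplet file
#'   or a dense TSV (first row gene ids, first column cell ids).
#' @param format `"mtx"` or `"dense"`.
#' @param labels_path two-column headerless TSV `cell_id <TAB> class`; must
#'   cover every cell in the matrix exactly once.
#' @param genes_path,cells_path sidecar files for `mtx` input (one id per
#'   line); default to `genes.tsv` / `cells.tsv` next to the matrix. MTX
#'   input may be stored genes x cells (the CellRanger convention);
#'   orientation is auto-detected from the sidecar lengths and the matrix is
#'   transposed to cells x genes. A square matrix is taken to be
#'   genes x cells.
#' @return an [expr_dataset()] with rows in matrix order.
#' @export
read_expression <- function(matrix_path, format = c("mtx", "dense"),
                            labels_path,
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stopf("matrix file not found: %s", matrix_path)
  if (!file.exists(labels_path)) stopf("labels file not found: %s", labels_path)

  if (format == "mtx") {
    dir <- dirname(matrix_path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    cells_path <- cells_path %||% file.path(dir, "cells.tsv")
    if (!file.exists(genes_path)) stopf("genes sidecar not found: %s", genes_path)
    if (!file.exists(cells_path)) stopf("cells sidecar not found: %s", cells_path)
    gene_ids <- read_tsv_col(genes_path)
    cell_ids <- read_tsv_col(cells_path)
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (nrow(m) == length(gene_ids) && ncol(m) == length(cell_ids)) {
      m <- t(m)                       # genes x cells on disk -> cells x genes
    } else if (nrow(m) == length(cell_ids) && ncol(m) == length(gene_ids)) {
      # already cells x genes
    } else {
      stopf("matrix is %d x %d but sidecars list %d genes and %d cells",
            nrow(m), ncol(m), length(gene_ids), length(cell_ids))
    }
  } else {
    tab <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE,
                             colClasses = "character")
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    gene_ids <- colnames(m)
    cell_ids <- rownames(m)
  }

  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           col.names = c("cell_id", "class"),
                           colClasses = "character", quote = "")
  if (anyDuplicated(lab$cell_id))
    stopf("labels file lists cell '%s' more than once",
          lab$cell_id[duplicated(lab$cell_id)][1])
  missing <- setdiff(cell_ids, lab$cell_id)
  if (length(missing) > 0)
    stopf("cell '%s' present in matrix but absent from labels", missing[1])
  labels <- lab$class[match(cell_ids, lab$cell_id)]
  expr_dataset(m, gene_ids = gene_ids, cell_ids = cell_ids, labels = labels)
}

#' Write a dataset to disk
#'
#' `mtx` output follows the CellRanger layout: `matrix.mtx` stored
#' genes x cells with `genes.tsv` / `cells.tsv` sidecars. `dense` output is
#' one TSV with gene ids in the first row and cell ids in the first column.
#' Both also write `labels.tsv` (`cell_id <TAB> class`). Round-tripping
#' through [read_expression()] is lossless up to float representation.
#'
#' @param ds an [expr_dataset()].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"dense"`.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(ds, dir, format = c("mtx", "dense")) {
  stopifnot(inherits(ds, "expr_dataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (format == "mtx") {
    mp <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(t(ds$values), sparse = TRUE),
                                "generalMatrix"), mp)
    writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(ds$cell_ids, file.path(dir, "cells.tsv"))
    paths <- c(mp, file.path(dir, c("genes.tsv", "cells.tsv")))
  } else {
    mp <- file.path(dir, "matrix.tsv")
    con <- file(mp, open = "wb")
    writeLines(paste(c("cell_id", ds$gene_ids), collapse = "\t"), con)
    body <- apply(ds$values, 1L, function(r)
      paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(ds$cell_ids, body, sep = "\t"), con)
    close(con)
    paths <- mp
  }
  lp <- file.path(dir, "labels.tsv")
  writeLines(paste(ds$cell_ids, as.character(ds$labels), sep = "\t"), lp)
  invisible(c(paths, lp))
}

#' Write / read a gene ranking as TSV
#'
#' The file has a `# method=... seed=...` comment line followed by a header
#' and columns `rank` (1-based), `gene_id`, `score`, plus any auxiliary
#' columns carried by the ranking (e.g. split gain). `read_ranking()`
#' composed with `write_ranking()` is the identity.
#'
#' @param r a [gene_ranking()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_ranking <- function(r, path) {
  stopifnot(inherits(r, "gene_ranking"))
  df <- data.frame(rank = seq_along(r$ordered_genes),
                   gene_id = r$ordered_genes,
                   score = r$scores, stringsAsFactors = FALSE)
  if (!is.null(r$extra)) df <- cbind(df, r$extra)
  con <- file(path, open = "wb")
  writeLines(sprintf("# method=%s seed=%s", r$method,
                     ifelse(is.na(r$seed), "NA", r$seed)), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, function(col)
    if (is.numeric(col)) format(col, trim = TRUE, digits = 15,
                                 scientific = FALSE) else as.character(col)),
    sep = "\t")), con)
  close(con)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stopf("ranking file not found: %s", path)
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec("^# method=(\\S+) seed=(\\S+)", first))[[1]]
  if (length(meta) != 3L) stopf("not a ranking file (missing method line): %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stopf("ranking file repeats gene '%s'", df$gene_id[duplicated(df$gene_id)][1])
  if (!identical(as.integer(df$rank), seq_len(nrow(df))))
    stopf("ranking file ranks are not 1..%d in order", nrow(df))
  extra_cols <- setdiff(colnames(df), c("rank", "gene_id", "score"))
  gene_ranking(method = meta[2],
               ordered_genes = df$gene_id, scores = df$score,
               seed = if (meta[3] == "NA") NA_integer_ else as.integer(meta[3]),
               extra = if (length(extra_cols)) df[extra_cols] else NULL)
}
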