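#' Venn-style intersection of selected gene sets
#'
#' Decomposes 2-5 gene sets (one per feature-ranking method, typically the
#' genes of each method's feasible-or-optimal random-forest classifier)
#' into their exact membership regions: every gene in the union is assigned
#' to the unique non-empty subset of methods that selected it, and every
#' region (all `2^M - 1` membership patterns) is counted.
#'
#' @param sets named list (2-5 entries) of non-empty character vectors.
#' @param consensus_min a gene supported by at least this many methods is
#'   flagged as a consensus gene (default 3).
#' @return a `consensus_report`: list with `per_method_sets`,
#'   `membership` (data.frame: `gene`, one logical column per method,
#'   `support`, `consensus`, ordered by decreasing support then gene id)
#'   and `region_counts` (data.frame `region`, `count` over all non-empty
#'   patterns, zeros included).
#' @export
venn_intersections <- function(sets, consensus_min = 3L) {
  if (!is.list(sets) || length(sets) == 0L) stopf("sets must be a non-empty list")
  if (length(sets) < 2L || length(sets) > 5L)
    stopf("between 2 and 5 sets are supported (got %d)", length(sets))
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("sets must be named by method")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stopf("sets must be non-empty")

  methods <- names(sets)
  all_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, methods))
  support <- rowSums(member)

  membership <- data.frame(gene = all_genes, member, check.names = FALSE)
  membership$support <- as.integer(support)
  membership$consensus <- support >= consensus_min
  membership <- membership[order(-membership$support, membership$gene), ,
                           drop = FALSE]
  rownames(membership) <- NULL

  # all 2^M - 1 non-empty membership patterns, e.g. "mrmr+pfi"
  M <- length(methods)
  patterns <- vapply(seq_len(2^M - 1L), function(code) {
    paste(methods[bitwAnd(code, 2^(seq_len(M) - 1L)) > 0], collapse = "+")
  }, character(1))
  gene_pattern <- apply(member, 1L, function(row)
    paste(methods[row], collapse = "+"))
  counts <- table(factor(gene_pattern, levels = patterns))
  region_counts <- data.frame(region = patterns,
                              count = as.integer(counts))

  structure(list(per_method_sets = sets, membership = membership,
                 region_counts = region_counts,
                 consensus_min = as.integer(consensus_min)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d methods, %d genes in union, %d consensus (>= %d methods)\n",
              length(x$per_method_sets), nrow(x$membership),
              sum(x$membership$consensus), x$consensus_min))
  nz <- x$region_counts[x$region_counts$count > 0, , drop = FALSE]
  print(nz, row.names = FALSE)
  invisible(x)
}

#' Write a consensus report (membership and region-count TSVs)
#'
#' @param report a `consensus_report`.
#' @param membership_path,regions_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_consensus <- function(report, membership_path, regions_path) {
  stopifnot(inherits(report, "consensus_report"))
  write_table_lf(report$membership, membership_path)
  write_table_lf(report$region_counts, regions_path)
  invisible(c(membership_path, regions_path))
}
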