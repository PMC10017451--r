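# If-then rule mining from fitted CART trees: one rule per leaf, formed by
# the conjunction of the split conditions on the root-to-leaf path, with
# same-gene conditions merged to the tightest interval.

#' Extract classification rules from a fitted decision tree
#'
#' Each leaf of the tree yields one rule: the conjunction of threshold
#' predicates (`gene <= t` or `gene > t`) met along the root-to-leaf path,
#' predicting the leaf's majority class. Conditions on the same gene are
#' merged (smallest upper bound, largest lower bound), so a rule carries at
#' most one `<=` and one `>` predicate per gene. The rules tile the feature
#' space: any sample satisfies exactly one rule.
#'
#' @param tree an `rpart` classification fit (trained with
#'   `maxcompete = 0, maxsurrogate = 0`, as produced by this package).
#' @param class_names optional class labels; default the tree's own.
#' @return a `rule_set`: list with `rules` (each a list `predicates`
#'   (data.frame `gene`, `cmp`, `threshold`), `predicted_class`, `support`,
#'   `purity`), `class_counts` (rules per class) and `n_leaves`.
#' @export
extract_rules <- function(tree, class_names = NULL) {
  if (!inherits(tree, "rpart")) stopf("tree must be an rpart fit")
  if (is.null(tree$frame)) stopf("tree is not trained")
  if (tree$method != "class") stopf("tree must be a classification tree")
  frame <- tree$frame
  class_names <- class_names %||% attr(tree, "ylevels")
  nodes <- as.integer(rownames(frame))
  L <- length(attr(tree, "ylevels"))
  counts <- frame$yval2[, 1L + seq_len(L), drop = FALSE]

  # map internal frame rows to their rows of tree$splits (primary splits
  # appear in frame order when competes/surrogates are disabled)
  internal <- which(frame$var != "<leaf>")
  split_row <- integer(nrow(frame))
  split_row[internal] <- seq_along(internal)

  rules <- list()
  walk <- function(row, preds) {
    if (frame$var[row] == "<leaf>") {
      cls <- class_names[frame$yval[row]]
      purity <- max(counts[row, ]) / sum(counts[row, ])
      rules[[length(rules) + 1L]] <<- list(
        predicates = merge_predicates(preds),
        predicted_class = cls,
        support = frame$n[row],
        purity = purity)
      return(invisible())
    }
    sp <- tree$splits[split_row[row], , drop = TRUE]
    gene <- as.character(frame$var[row])
    cut <- sp[["index"]]
    kid_l <- match(nodes[row] * 2L, nodes)
    kid_r <- match(nodes[row] * 2L + 1L, nodes)
    if (sp[["ncat"]] < 0) {            # left branch takes values below cut
      walk(kid_l, rbind(preds, data.frame(gene = gene, cmp = "<=",
                                          threshold = cut)))
      walk(kid_r, rbind(preds, data.frame(gene = gene, cmp = ">",
                                          threshold = cut)))
    } else {                           # left branch takes values above cut
      walk(kid_l, rbind(preds, data.frame(gene = gene, cmp = ">",
                                          threshold = cut)))
      walk(kid_r, rbind(preds, data.frame(gene = gene, cmp = "<=",
                                          threshold = cut)))
    }
  }
  empty <- data.frame(gene = character(), cmp = character(),
                      threshold = numeric())
  walk(1L, empty)

  cc <- table(factor(vapply(rules, `[[`, character(1), "predicted_class"),
                     levels = class_names))
  structure(list(rules = rules, class_counts = cc,
                 n_leaves = sum(frame$var == "<leaf>")),
            class = "rule_set")
}

# tightest interval per gene: min of upper bounds, max of lower bounds
merge_predicates <- function(preds) {
  if (nrow(preds) == 0L) return(preds)
  out <- list()
  for (g in unique(preds$gene)) {
    pg <- preds[preds$gene == g, , drop = FALSE]
    up <- pg$threshold[pg$cmp == "<="]
    lo <- pg$threshold[pg$cmp == ">"]
    if (length(lo) > 0)
      out[[length(out) + 1L]] <- data.frame(gene = g, cmp = ">",
                                            threshold = max(lo))
    if (length(up) > 0)
      out[[length(out) + 1L]] <- data.frame(gene = g, cmp = "<=",
                                            threshold = min(up))
  }
  do.call(rbind, out)
}

#' Apply a rule set to one sample
#'
#' Evaluates every rule on the sample (boundary convention: a value equal
#' to a `<=` threshold satisfies it) and returns the predicted class of the
#' single satisfied rule. A correctly extracted rule set tiles the feature
#' space, so zero or multiple matches indicate an extraction bug and raise
#' an error.
#'
#' @param rs a `rule_set` from [extract_rules()].
#' @param sample named numeric vector (or single-row data) covering every
#'   gene the rules reference.
#' @return the predicted class label (character).
#' @export
apply_rules <- function(rs, sample) {
  stopifnot(inherits(rs, "rule_set"))
  sample <- unlist(sample)
  hit <- which(vapply(rs$rules, function(r) {
    p <- r$predicates
    if (nrow(p) == 0L) return(TRUE)
    v <- sample[p$gene]
    if (anyNA(v)) stopf("sample does not cover gene '%s'",
                        p$gene[is.na(v)][1])
    all(ifelse(p$cmp == "<=", v <= p$threshold, v > p$threshold))
  }, logical(1)))
  if (length(hit) != 1L)
    stopf("internal consistency error: %d rules satisfied (expected 1)",
          length(hit))
  rs$rules[[hit]]$predicted_class
}

#' Train the rule-mining tree and extract its rules
#'
#' Trains a full-depth CART tree on the SMOTE-balanced full dataset
#' restricted to the top genes of a ranking (the optimal DT subset) and
#' extracts its if-then rules.
#'
#' @param ds an [expr_dataset()].
#' @param ranking a [gene_ranking()].
#' @param subset_size number of top genes to use.
#' @param smote_k SMOTE neighbor count.
#' @param seed integer seed (drives SMOTE).
#' @return a list with `rule_set` and the fitted `tree`.
#' @export
mine_rules <- function(ds, ranking, subset_size, smote_k = 5L, seed = 0L) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ranking, "gene_ranking"))
  genes <- ranking$ordered_genes[seq_len(subset_size)]
  sub <- ds$values[, genes, drop = FALSE]
  bal <- smote_balance(sub, ds$labels, k = smote_k, seed = seed)
  tree <- train_dt(bal$values, bal$labels)
  list(rule_set = extract_rules(tree), tree = tree)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules over %d leaves\n",
              length(x$rules), x$n_leaves))
  print(x$class_counts)
  invisible(x)
}

#' Format rules for human reading
#'
#' One line per rule in the style
#' `Rule 1: (G0007 <= 3.90) and (G0002 > 1.25) => ChAd-BNT (support 123,
#' purity 0.97)`, thresholds rounded to two decimals.
#'
#' @param rs a `rule_set`.
#' @return character vector, one element per rule.
#' @export
format_rules <- function(rs) {
  stopifnot(inherits(rs, "rule_set"))
  vapply(seq_along(rs$rules), function(i) {
    r <- rs$rules[[i]]
    cond <- if (nrow(r$predicates) == 0L) "(always)" else
      paste(sprintf("(%s %s %.2f)", r$predicates$gene, r$predicates$cmp,
                    r$predicates$threshold), collapse = " and ")
    sprintf("Rule %d: %s => %s (support %d, purity %.2f)",
            i, cond, r$predicted_class, r$support, r$purity)
  }, character(1))
}

#' Write a rule set as TSV (full precision) plus counts
#'
#' @param rs a `rule_set`.
#' @param path TSV path; one row per (rule, predicate). Rules without
#'   predicates emit one row with empty predicate fields.
#' @return invisibly, `path`.
#' @export
write_rules <- function(rs, path) {
  rows <- list()
  for (i in seq_along(rs$rules)) {
    r <- rs$rules[[i]]
    p <- r$predicates
    if (nrow(p) == 0L)
      p <- data.frame(gene = "", cmp = "", threshold = NA_real_)
    rows[[i]] <- data.frame(rule_id = i, predicate_index = seq_len(nrow(p)),
                            gene = p$gene, cmp = p$cmp,
                            threshold = p$threshold,
                            class = r$predicted_class, support = r$support,
                            purity = r$purity)
  }
  write_table_lf(do.call(rbind, rows), path)
  invisible(path)
}
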