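# The five feature-ranking algorithms. Each returns a gene_ranking whose
# order is reproducible: ties are always broken by original gene index.

#' Rank genes by max-relevance min-redundancy (mRMR)
#'
#' Genes are discretized to three states ([discretize_gene()]) and ranked by
#' the greedy mRMR procedure: the first gene maximizes mutual information
#' with the class label; each later gene `g` maximizes
#' `MI(g, label) - mean over selected s of MI(g, s)` (the MID difference
#' criterion) or `MI(g, label) / mean MI(g, s)` (MIQ quotient) over the
#' already-selected set. Deterministic; ties break toward the smaller
#' original gene index.
#'
#' @param ds an [expr_dataset()].
#' @param top_n how many genes to order (defaults to all).
#' @param criterion `"mid"` (difference, default) or `"miq"` (quotient).
#' @return a [gene_ranking()] with the criterion value at selection as the
#'   score (relevance for the first gene).
#' @export
rank_mrmr <- function(ds, top_n = ncol(ds$values),
                      criterion = c("mid", "miq")) {
  stopifnot(inherits(ds, "expr_dataset"))
  criterion <- match.arg(criterion)
  p <- ncol(ds$values)
  if (top_n <= 0) stopf("top_n must be positive")
  if (top_n > p) stopf("top_n (%d) exceeds the number of genes (%d)", top_n, p)
  top_n <- as.integer(top_n)

  disc <- apply(ds$values, 2L, discretize_codes)   # cells x genes, codes 1..3
  yi <- as.integer(ds$labels)
  ky <- nlevels(ds$labels)

  relevance <- vapply(seq_len(p), function(j) mi_codes(disc[, j], 3L, yi, ky),
                      numeric(1))
  selected <- integer(top_n)
  scores <- numeric(top_n)
  red_sum <- numeric(p)      # running sum of MI(g, s) over selected s
  in_set <- logical(p)

  for (step in seq_len(top_n)) {
    if (step == 1L) {
      crit <- relevance
    } else {
      red_mean <- red_sum / (step - 1L)
      crit <- if (criterion == "mid") relevance - red_mean
              else relevance / pmax(red_mean, .Machine$double.eps)
    }
    crit[in_set] <- -Inf
    pick <- which.max(crit)                # first max = smallest gene index
    selected[step] <- pick
    scores[step] <- crit[pick]
    in_set[pick] <- TRUE
    if (step < top_n) {
      upd <- which(!in_set)
      xp <- disc[, pick]
      red_sum[upd] <- red_sum[upd] +
        vapply(upd, function(j) mi_codes(disc[, j], 3L, xp, 3L), numeric(1))
    }
  }
  gene_ranking("mrmr", ds$gene_ids[selected], scores)
}

#' Parameters for Monte Carlo feature selection
#'
#' @param s number of random gene projections.
#' @param t decision trees per projection.
#' @param m genes per projection (default `ceiling(0.05 * n_genes)`,
#'   resolved at run time when `NULL`).
#' @param u,v non-negative exponents weighting tree accuracy and node mass
#'   in the relative-importance score.
#' @param boot_fraction fraction of cells used to train each tree; the
#'   held-out cells provide the tree's weighted accuracy.
#' @param seed integer seed.
#' @return an object of class `mcfs_params`.
#' @export
mcfs_params <- function(s = 200L, t = 5L, m = NULL, u = 1, v = 1,
                        boot_fraction = 0.66, seed = 0L) {
  if (s < 1L || t < 1L) stopf("s and t must be positive integers")
  if (!is.null(m) && m < 1L) stopf("m must be positive")
  if (u < 0 || v < 0) stopf("u and v must be non-negative")
  if (boot_fraction <= 0 || boot_fraction >= 1)
    stopf("boot_fraction must lie in (0, 1)")
  structure(list(s = as.integer(s), t = as.integer(t),
                 m = if (is.null(m)) NULL else as.integer(m),
                 u = u, v = v, boot_fraction = boot_fraction,
                 seed = as.integer(seed)),
            class = "mcfs_params")
}

# Gini impurity from a vector of class counts
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Per-gene sum over an rpart tree's internal nodes of
# IG(node) * (n_node / n_root)^v, where IG is the Gini impurity decrease of
# the split. Works off the class-count table in frame$yval2.
mcfs_tree_contributions <- function(fit, v) {
  frame <- fit$frame
  internal <- which(frame$var != "<leaf>")
  out <- numeric(0)
  if (length(internal) == 0L) return(out)
  nodes <- as.integer(rownames(frame))
  L <- length(attr(fit, "ylevels"))
  counts <- frame$yval2[, 1L + seq_len(L), drop = FALSE]
  n_root <- frame$n[1]
  contrib <- numeric(length(internal))
  for (i in seq_along(internal)) {
    row <- internal[i]
    kid_l <- match(nodes[row] * 2L, nodes)
    kid_r <- match(nodes[row] * 2L + 1L, nodes)
    n_p <- frame$n[row]
    ig <- gini_impurity(counts[row, ]) -
      (frame$n[kid_l] / n_p) * gini_impurity(counts[kid_l, ]) -
      (frame$n[kid_r] / n_p) * gini_impurity(counts[kid_r, ])
    contrib[i] <- ig * (n_p / n_root)^v
  }
  vapply(split(contrib, as.character(frame$var[internal])), sum, numeric(1))
}

# mean per-class recall (balanced accuracy) over classes present in y_true
weighted_accuracy <- function(y_true, y_pred) {
  present <- levels(droplevels(y_true))
  recalls <- vapply(present, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1))
  mean(recalls)
}

#' Rank genes by Monte Carlo feature selection (MCFS)
#'
#' Builds `s` random projections of `m` genes; on each projection trains `t`
#' CART trees on random subsamples of the cells (the held-out cells give the
#' tree's weighted accuracy, wAcc, defined as the mean per-class recall).
#' The relative importance of gene `g` is
#' `RI_g = sum over trees of wAcc^u * sum over nodes splitting on g of
#' IG(node) * (n_node / n_root)^v`, with IG the Gini impurity decrease.
#' Genes never selected by any tree score exactly 0. Genes are ordered by
#' non-increasing RI, ties by gene index.
#'
#' @param ds an [expr_dataset()].
#' @param params an [mcfs_params()].
#' @return a [gene_ranking()] with RI scores.
#' @export
rank_mcfs <- function(ds, params = mcfs_params()) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(params, "mcfs_params"))
  p <- ncol(ds$values)
  n <- nrow(ds$values)
  m <- params$m %||% max(1L, ceiling(0.05 * p))
  if (m > p) stopf("m (%d) exceeds the number of genes (%d)", m, p)
  ctrl <- rpart::rpart.control(cp = 0, xval = 0, minsplit = 2, minbucket = 1,
                               maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  ri <- stats::setNames(numeric(p), ds$gene_ids)
  n_train <- max(2L, floor(params$boot_fraction * n))

  with_seed(params$seed, {
    for (proj in seq_len(params$s)) {
      genes <- sample.int(p, m)
      sub <- ds$values[, genes, drop = FALSE]
      df <- as.data.frame(sub)
      df$.class <- ds$labels
      for (tr in seq_len(params$t)) {
        idx <- sample.int(n, n_train)
        fit <- rpart::rpart(.class ~ ., data = df[idx, , drop = FALSE],
                            method = "class",
                            parms = list(split = "gini"), control = ctrl)
        hold <- df[-idx, , drop = FALSE]
        wacc <- if (nrow(hold) > 0) {
          pred <- stats::predict(fit, hold, type = "class")
          weighted_accuracy(hold$.class, pred)
        } else 1
        contrib <- mcfs_tree_contributions(fit, params$v)
        if (length(contrib) > 0)
          ri[names(contrib)] <- ri[names(contrib)] + wacc^params$u * contrib
      }
    }
  })
  ord <- order_desc_stable(ri)
  gene_ranking("mcfs", ds$gene_ids[ord], ri[ord], seed = params$seed)
}

#' Rank genes by L1-penalised one-vs-rest model coefficients
#'
#' Fits one L1-penalised (lasso) logistic model per class against the rest
#' on standardized gene values at a fixed penalty, and scores each gene by
#' the largest absolute coefficient it attains across classes. Zero-
#' coefficient genes keep their input order. The penalty applies to the
#' mean (per-sample) log-likelihood, so the ranking is invariant to
#' duplicating every cell. Deterministic.
#'
#' @param ds an [expr_dataset()] with at least two classes.
#' @param lambda penalty on the mean log-likelihood scale (default 0.01, a
#'   mild penalty that zeroes most null genes while retaining genes with
#'   real class shifts).
#' @return a [gene_ranking()] with max-|coefficient| scores.
#' @export
rank_lasso <- function(ds, lambda = 0.01) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (n_classes(ds) < 2L) stopf("rank_lasso needs at least two classes")
  score <- stats::setNames(numeric(ncol(ds$values)), ds$gene_ids)
  for (cl in levels(ds$labels)) {
    yy <- as.numeric(ds$labels == cl)
    fit <- glmnet::glmnet(ds$values, yy, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = TRUE)
    beta <- abs(as.numeric(fit$beta))
    score <- pmax(score, beta)
  }
  ord <- order_desc_stable(score)
  gene_ranking("lasso", ds$gene_ids[ord], score[ord])
}

#' Rank genes by gradient-boosted-tree split counts
#'
#' Trains a multiclass gradient-boosted decision-tree ensemble and scores
#' each gene by its total split count over all trees
#' (`T_Split = sum over trees of per-tree splits`); the total split gain
#' (`T_Gain`) is computed and carried alongside in the ranking's `extra`
#' column but never used for ordering. Genes with no splits score 0 and
#' keep their input order.
#'
#' @param ds an [expr_dataset()] with at least two classes.
#' @param n_rounds boosting iterations (default 100).
#' @param seed integer seed (the default booster settings are deterministic;
#'   the seed is recorded for provenance).
#' @return a [gene_ranking()] with split-count scores and a `gain` column.
#' @export
rank_gbdt_split <- function(ds, n_rounds = 100L, seed = 0L) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (n_rounds < 1L) stopf("n_rounds must be >= 1")
  L <- n_classes(ds)
  if (L < 2L) stopf("rank_gbdt_split needs at least two classes")
  dtrain <- xgboost::xgb.DMatrix(ds$values,
                                 label = as.integer(ds$labels) - 1L)
  params <- list(objective = if (L > 2L) "multi:softprob" else "binary:logistic",
                 nthread = 1L, seed = as.integer(seed))
  if (L > 2L) params$num_class <- L
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = as.integer(n_rounds), verbose = 0)
  tree_tab <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  internal <- tree_tab[tree_tab$Feature != "Leaf", , drop = FALSE]
  splits <- stats::setNames(numeric(ncol(ds$values)), ds$gene_ids)
  gains <- splits
  if (nrow(internal) > 0) {
    cnt <- table(internal$Feature)
    splits[names(cnt)] <- as.numeric(cnt)
    gg <- tapply(internal$Gain, internal$Feature, sum)
    gains[names(gg)] <- as.numeric(gg)
  }
  ord <- order_desc_stable(splits)
  gene_ranking("gbdt_split", ds$gene_ids[ord], splits[ord],
               seed = as.integer(seed),
               extra = data.frame(gain = gains[ord]))
}

#' Parameters for permutation feature importance
#'
#' @param K permutation repetitions per gene.
#' @param error_measure currently `"misclassification"`.
#' @param mode `"ratio"` scores a gene as `e_perm / e_base` (the default);
#'   `"difference"` as `e_perm - e_base`.
#' @param n_trees trees in the underlying random forest.
#' @param seed integer seed.
#' @return an object of class `pfi_params`.
#' @export
pfi_params <- function(K = 5L, error_measure = "misclassification",
                       mode = c("ratio", "difference"), n_trees = 100L,
                       seed = 0L) {
  if (K < 1L) stopf("K must be >= 1")
  error_measure <- match.arg(error_measure, "misclassification")
  structure(list(K = as.integer(K), error_measure = error_measure,
                 mode = match.arg(mode), n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "pfi_params")
}

# flatten a ranger forest into parallel arrays for the C++ traversal kernel
flatten_forest <- function(rf) {
  Tn <- rf$num.trees
  left <- right <- svar <- pred <- integer(0)
  sval <- numeric(0)
  offsets <- integer(Tn + 1L)
  for (t in seq_len(Tn)) {
    ti <- ranger::treeInfo(rf, t)
    off <- length(left)
    offsets[t] <- off
    term <- ti$terminal
    left <- c(left, ifelse(term, -1L, ti$leftChild))
    right <- c(right, ifelse(term, -1L, ti$rightChild))
    svar <- c(svar, ifelse(term, -1L, ti$splitvarID))
    sval <- c(sval, ifelse(term, 0, ti$splitval))
    pr <- ti$prediction
    pred <- c(pred, ifelse(term, as.integer(factor(pr, levels = rf$forest$levels)), -1L))
  }
  offsets[Tn + 1L] <- length(left)
  list(offsets = offsets, left = left, right = right, svar = svar,
       sval = sval, pred = pred, n_trees = Tn)
}

#' Rank genes by permutation feature importance (PFI)
#'
#' Fits a random forest `f` to the full dataset, measures its baseline
#' misclassification rate `e_base` on the same data (forest votes
#' aggregated by majority, ties to the first class level), then for each
#' gene `j` and repetition `k` shuffles column `j`, recomputes the error
#' `e_jk`, and scores the gene by the mean of `I_jk = e_jk / e_base`
#' (ratio form; a difference form is available via [pfi_params()]). When
#' the baseline error is exactly 0 it is replaced by `1 / (2 n_cells)` so
#' the ratios stay finite. Only trees that actually split on gene `j` are
#' re-evaluated, which keeps the permutation sweep fast.
#'
#' @param ds an [expr_dataset()].
#' @param params a [pfi_params()].
#' @return a [gene_ranking()] with mean-importance scores.
#' @export
rank_pfi <- function(ds, params = pfi_params()) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(params, "pfi_params"))
  X <- ds$values
  n <- nrow(X)
  p <- ncol(X)
  L <- n_classes(ds)
  yi <- as.integer(ds$labels)
  rf <- ranger::ranger(x = X, y = ds$labels, num.trees = params$n_trees,
                       seed = params$seed, num.threads = 1L)
  fo <- flatten_forest(rf)
  base_votes <- cpp_forest_votes(fo$offsets, fo$left, fo$right, fo$svar,
                                 fo$sval, fo$pred, X)
  base_counts <- cpp_vote_counts(base_votes, L)
  base_pred <- max.col(base_counts, ties.method = "first")
  e_base <- mean(base_pred != yi)
  if (e_base == 0) e_base <- 1 / (2 * n)

  # per (tree, gene): the rows whose baseline path crosses the gene; only
  # those can change leaf when the gene's column is permuted
  touch <- cpp_touch_lists(fo$offsets, fo$left, fo$right, fo$svar, fo$sval,
                           fo$pred, X)
  by_gene <- vector("list", p)   # per gene: list(trees = 0-based, rows = list)
  for (t in seq_len(fo$n_trees)) {
    tl <- touch[[t]]
    vars <- tl$vars
    for (vi in seq_along(vars)) {
      j <- vars[vi] + 1L
      rows <- tl$rows[(tl$offsets[vi] + 1L):tl$offsets[vi + 1L]]
      if (is.null(by_gene[[j]]))
        by_gene[[j]] <- list(trees = integer(0), rows = list())
      by_gene[[j]]$trees <- c(by_gene[[j]]$trees, t - 1L)
      by_gene[[j]]$rows[[length(by_gene[[j]]$rows) + 1L]] <- rows
    }
  }

  scores <- with_seed(params$seed, {
    vapply(seq_len(p), function(j) {
      bg <- by_gene[[j]]
      if (is.null(bg)) {
        e_perm <- rep(e_base, params$K)   # no tree path touches the gene
      } else {
        perms <- vapply(seq_len(params$K), function(k) sample.int(n),
                        integer(n))
        e_perm <- cpp_pfi_gene(fo$offsets, fo$left, fo$right, fo$svar,
                               fo$sval, fo$pred, X, j - 1L, perms,
                               base_votes, base_counts, yi,
                               bg$trees, bg$rows, L)
      }
      if (params$mode == "ratio") mean(e_perm / e_base)
      else mean(e_perm - e_base)
    }, numeric(1))
  })
  ord <- order_desc_stable(scores)
  gene_ranking("pfi", ds$gene_ids[ord], scores[ord], seed = params$seed)
}

#' Run all five rankers
#'
#' @param ds an [expr_dataset()].
#' @param methods subset of `c("mrmr", "mcfs", "lasso", "gbdt_split",
#'   "pfi")`.
#' @param top_n genes to order for mRMR (defaults to all; the other four
#'   methods always score every gene).
#' @param mcfs,pfi parameter objects for the seeded rankers.
#' @param gbdt_rounds boosting iterations for the split-count ranker.
#' @param lambda penalty for the lasso ranker (`NULL` = default).
#' @param seed base seed; per-ranker seeds are derived from it via
#'   [derive_seed()] unless the parameter objects carry explicit seeds.
#' @return a named list of [gene_ranking()]s.
#' @export
rank_all <- function(ds,
                     methods = c("mrmr", "mcfs", "lasso", "gbdt_split", "pfi"),
                     top_n = ncol(ds$values),
                     mcfs = NULL, pfi = NULL, gbdt_rounds = 100L,
                     lambda = NULL, seed = 0L) {
  methods <- match.arg(methods, several.ok = TRUE)
  mcfs <- mcfs %||% mcfs_params(seed = derive_seed(seed, 11L))
  pfi <- pfi %||% pfi_params(seed = derive_seed(seed, 13L))
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      mrmr = rank_mrmr(ds, top_n = top_n),
      mcfs = rank_mcfs(ds, mcfs),
      lasso = if (is.null(lambda)) rank_lasso(ds)
              else rank_lasso(ds, lambda = lambda),
      gbdt_split = rank_gbdt_split(ds, n_rounds = gbdt_rounds,
                                   seed = derive_seed(seed, 12L)),
      pfi = rank_pfi(ds, pfi))
  }
  out
}
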