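# Incremental feature selection: sweep nested top-k prefixes of a gene
# ranking, score a classifier on each prefix under stratified 10-fold CV
# with SMOTE-balanced training folds, and pick optimal/feasible subsets.

rpart_ctrl <- function() {
  rpart::rpart.control(cp = 0, xval = 0, minsplit = 2, minbucket = 1,
                       maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
}

# full-depth CART (Gini) on a matrix + factor; returns the rpart fit
train_dt <- function(X, y) {
  df <- as.data.frame(X)
  df$.class <- y
  rpart::rpart(.class ~ ., data = df, method = "class",
               parms = list(split = "gini"), control = rpart_ctrl())
}

predict_dt <- function(fit, X) {
  stats::predict(fit, as.data.frame(X), type = "class")
}

train_rf <- function(X, y, n_trees, seed) {
  ranger::ranger(x = X, y = y, num.trees = n_trees, seed = seed,
                 num.threads = 1L)
}

predict_rf <- function(fit, X, seed = 1L) {
  # predict.ranger draws a seed from the global RNG unless given one
  stats::predict(fit, data = X, num.threads = 1L, seed = seed)$predictions
}

# seeded stratified fold assignment; every class must have >= folds members
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds)
        stopf("class '%s' has %d cells but %d folds were requested",
              cl, length(idx), folds)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Run incremental feature selection for one (ranking, classifier) pair
#'
#' For each subset size `k` in `step, 2 step, ...` up to
#' `min(cap, length(ranking))`, the dataset is restricted to the top-`k`
#' genes of the ranking and the classifier is evaluated by stratified
#' `folds`-fold cross-validation: within each fold the training portion
#' (only) is SMOTE-balanced to the majority class, the classifier is
#' trained, and the untouched test portion is predicted. Test predictions
#' are pooled over all folds into a single [evaluate()] call per subset
#' size. The fold split is fixed across subset sizes, so curves are
#' comparable point to point. Identical inputs and seed give an identical
#' curve.
#'
#' @param ds an [expr_dataset()].
#' @param ranking a [gene_ranking()] covering at least `step` genes of `ds`.
#' @param classifier `"dt"` (full-depth CART, Gini) or `"rf"` (random
#'   forest).
#' @param step subset-size increment (default 10).
#' @param cap largest subset size considered (default 5000; truncated to
#'   the ranking length).
#' @param folds cross-validation folds (default 10).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param rf_trees trees per random forest (default 100).
#' @param seed integer seed driving fold assignment, SMOTE and the forests.
#' @param delta,min_optimal_size feasibility parameters passed to
#'   [select_feasible()].
#' @return an `ifs_curve`: list with `ranking_method`, `classifier`,
#'   `records` (each a list `subset_size`, `classifier`, `eval`),
#'   `optimal_index`, `feasible_index` (`NA` when none), and the sweep
#'   parameters.
#' @export
run_ifs <- function(ds, ranking, classifier = c("dt", "rf"), step = 10L,
                    cap = 5000L, folds = 10L, smote_k = 5L, rf_trees = 100L,
                    seed = 0L, delta = 0.015, min_optimal_size = 100L) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ranking, "gene_ranking"))
  classifier <- match.arg(classifier)
  if (folds < 2L) stopf("folds must be >= 2")
  genes <- ranking$ordered_genes
  if (!all(genes %in% ds$gene_ids))
    stopf("ranking refers to genes absent from the dataset")
  if (length(genes) < step)
    stopf("ranking (%d genes) is shorter than one step (%d)",
          length(genes), step)
  limit <- min(cap, length(genes))
  sizes <- seq.int(step, limit, by = step)
  if (limit %% step != 0L && limit == cap) sizes <- c(sizes, limit)

  fold_of <- stratified_folds(ds$labels, folds, derive_seed(seed, 1L))
  n <- nrow(ds$values)
  records <- vector("list", length(sizes))

  for (si in seq_along(sizes)) {
    k <- sizes[si]
    sub <- ds$values[, genes[seq_len(k)], drop = FALSE]
    pred <- factor(rep(NA_character_, n), levels = levels(ds$labels))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      bal <- smote_balance(sub[!test, , drop = FALSE], ds$labels[!test],
                           k = smote_k, seed = derive_seed(seed, 2L, si, f))
      if (classifier == "dt") {
        fit <- train_dt(bal$values, bal$labels)
        pred[test] <- predict_dt(fit, sub[test, , drop = FALSE])
      } else {
        fit <- train_rf(bal$values, bal$labels, rf_trees,
                        derive_seed(seed, 3L, si, f))
        pred[test] <- predict_rf(fit, sub[test, , drop = FALSE],
                                 seed = derive_seed(seed, 6L, si, f))
      }
    }
    stopifnot(!anyNA(pred))
    records[[si]] <- list(subset_size = k, classifier = classifier,
                          eval = evaluate(ds$labels, pred))
  }

  curve <- structure(
    list(ranking_method = ranking$method, classifier = classifier,
         records = records, step = as.integer(step), cap = as.integer(cap),
         folds = as.integer(folds), seed = as.integer(seed),
         optimal_index = NA_integer_, feasible_index = NA_integer_),
    class = "ifs_curve"
  )
  curve$optimal_index <- select_optimal(curve)
  curve$feasible_index <- select_feasible(curve, delta = delta,
                                          min_optimal_size = min_optimal_size)
  curve
}

curve_wf1 <- function(curve) {
  vapply(curve$records, function(r) r$eval$weighted_f1, numeric(1))
}

curve_sizes <- function(curve) {
  vapply(curve$records, function(r) r$subset_size, numeric(1))
}

#' Select the optimal record of an IFS curve
#'
#' The record with the maximum weighted F1; ties go to the smallest subset
#' size.
#'
#' @param curve an `ifs_curve` from [run_ifs()].
#' @return 1-based record index.
#' @export
select_optimal <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"))
  if (length(curve$records) == 0L) stopf("empty IFS curve")
  which.max(curve_wf1(curve))   # first max = smallest size (sizes increase)
}

#' Select the feasible record of an IFS curve
#'
#' A feasible classifier trades a small loss of weighted F1 for a much
#' smaller gene subset. It is only sought when the optimal subset is large
#' (`> min_optimal_size` genes); it is then the smallest subset whose
#' weighted F1 is within `delta` of the optimum, and `NA` when only the
#' optimum itself qualifies.
#'
#' @param curve an `ifs_curve`.
#' @param delta non-negative weighted-F1 tolerance (default 0.015).
#' @param min_optimal_size optimal sizes at or below this never get a
#'   feasible companion (default 100).
#' @return 1-based record index, or `NA_integer_` when no feasible record
#'   exists.
#' @export
select_feasible <- function(curve, delta = 0.015, min_optimal_size = 100L) {
  stopifnot(inherits(curve, "ifs_curve"))
  if (delta < 0) stopf("delta must be non-negative")
  opt <- select_optimal(curve)
  sizes <- curve_sizes(curve)
  if (sizes[opt] <= min_optimal_size) return(NA_integer_)
  wf1 <- curve_wf1(curve)
  ok <- which(wf1 >= wf1[opt] - delta)
  cand <- ok[which.min(sizes[ok])]
  if (cand == opt) NA_integer_ else cand
}

#' @export
print.ifs_curve <- function(x, ...) {
  wf1 <- curve_wf1(x)
  sizes <- curve_sizes(x)
  cat(sprintf("<ifs_curve> %s + %s: %d subset sizes (%d..%d)\n",
              x$ranking_method, x$classifier, length(sizes),
              min(sizes), max(sizes)))
  cat(sprintf("optimal: weighted F1 %.4f at %d genes\n",
              wf1[x$optimal_index], sizes[x$optimal_index]))
  if (!is.na(x$feasible_index))
    cat(sprintf("feasible: weighted F1 %.4f at %d genes\n",
                wf1[x$feasible_index], sizes[x$feasible_index]))
  invisible(x)
}

#' Run the full IFS matrix: every ranking with both classifiers
#'
#' @param ds an [expr_dataset()].
#' @param rankings named list of [gene_ranking()]s.
#' @param classifiers character subset of `c("dt", "rf")`.
#' @param ... sweep parameters forwarded to [run_ifs()].
#' @param seed base seed; each (ranking, classifier) pair derives its own.
#' @return a list with `curves` (named `<method>_<classifier>`) and
#'   `summary`, a data.frame with one row per optimal record and one
#'   starred row per feasible record, shaped like the study's performance
#'   tables (per-class F1, ACC, MCC, macro and weighted F1).
#' @export
run_matrix <- function(ds, rankings, classifiers = c("dt", "rf"), ...,
                       seed = 0L) {
  stopifnot(is.list(rankings), length(rankings) > 0)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  curves <- list()
  i <- 0L
  for (rk in rankings) {
    for (clf in classifiers) {
      i <- i + 1L
      curves[[paste(rk$method, clf, sep = "_")]] <-
        run_ifs(ds, rk, classifier = clf, ...,
                seed = derive_seed(seed, 4L, i))
    }
  }
  list(curves = curves, summary = ifs_summary(curves))
}

#' Summarize IFS curves as a performance table
#'
#' @param curves list of `ifs_curve` objects.
#' @return data.frame with columns `ranking`, `classifier` (feasible rows
#'   starred as e.g. `"rf*"`), `n_features`, one per-class F1 column per
#'   class, `ACC`, `MCC`, `macro_F1`, `weighted_F1`.
#' @export
ifs_summary <- function(curves) {
  rows <- list()
  for (cv in curves) {
    take <- c(optimal = cv$optimal_index)
    if (!is.na(cv$feasible_index)) take <- c(take, feasible = cv$feasible_index)
    for (nm in names(take)) {
      rec <- cv$records[[take[[nm]]]]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(ranking = cv$ranking_method,
                   classifier = paste0(cv$classifier,
                                       if (nm == "feasible") "*" else ""),
                   n_features = rec$subset_size),
        eval_to_row(rec$eval))
    }
  }
  do.call(rbind, rows)
}

#' Write an IFS curve as TSV (one row per subset size)
#'
#' @param curve an `ifs_curve`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  rows <- do.call(rbind, lapply(curve$records, function(r)
    cbind(data.frame(ranking = curve$ranking_method,
                     classifier = curve$classifier,
                     subset_size = r$subset_size),
          eval_to_row(r$eval))))
  rows$optimal <- seq_len(nrow(rows)) == curve$optimal_index
  rows$feasible <- !is.na(curve$feasible_index) &
    seq_len(nrow(rows)) == curve$feasible_index
  write_table_lf(rows, path)
  invisible(path)
}

# deterministic TSV writer (LF endings, full precision)
write_table_lf <- function(df, path) {
  con <- file(path, open = "wb")
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col)
      if (is.numeric(col)) format(col, trim = TRUE, digits = 15,
                                   scientific = FALSE)
      else as.character(col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  close(con)
  invisible(path)
}
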