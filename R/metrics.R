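#' Multiclass classification metrics
#'
#' Computes the full evaluation suite from true and predicted labels:
#' per-class precision, recall and F1 (zero when their denominator is
#' zero), accuracy, macro F1 (unweighted mean of per-class F1), weighted F1
#' (class-proportion-weighted mean, the headline measure), and the
#' multiclass Matthews correlation coefficient in its covariance form:
#' `MCC = cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))` on the one-hot true /
#' predicted indicator matrices, defined as 0 when either variance term
#' vanishes (e.g. a constant prediction).
#'
#' @param y_true true labels; their (factor) level set defines the classes.
#' @param y_pred predicted labels, drawn from the same set.
#' @return an object of class `eval_result`: list with `per_class_precision`,
#'   `per_class_recall`, `per_class_f1`, `accuracy`, `macro_f1`,
#'   `weighted_f1`, `mcc`, `class_weights`, `n_classes`, `confusion`.
#' @export
evaluate <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred must have equal length")
  if (length(y_true) == 0L) stopf("empty label vectors")
  y_true <- if (is.factor(y_true)) droplevels(y_true) else factor(y_true)
  classes <- levels(y_true)
  bad <- setdiff(unique(as.character(y_pred)), classes)
  if (length(bad) > 0)
    stopf("predicted label '%s' not in the true label set", bad[1])
  y_pred <- factor(as.character(y_pred), levels = classes)
  L <- length(classes)
  n <- length(y_true)

  conf <- table(true = y_true, pred = y_pred)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- as.numeric(table(y_true)) / n

  Xh <- stats::model.matrix(~ y_true - 1)
  Yh <- stats::model.matrix(~ y_pred - 1)
  cxy <- sum((Xh - rep(colMeans(Xh), each = n)) *
             (Yh - rep(colMeans(Yh), each = n)))
  cxx <- sum((Xh - rep(colMeans(Xh), each = n))^2)
  cyy <- sum((Yh - rep(colMeans(Yh), each = n))^2)
  mcc <- if (cxx > 0 && cyy > 0) cxy / sqrt(cxx * cyy) else 0

  structure(
    list(per_class_precision = stats::setNames(as.numeric(precision), classes),
         per_class_recall = stats::setNames(as.numeric(recall), classes),
         per_class_f1 = stats::setNames(as.numeric(f1), classes),
         accuracy = sum(tp) / n,
         macro_f1 = mean(f1),
         weighted_f1 = sum(w * f1),
         mcc = mcc,
         class_weights = stats::setNames(w, classes),
         n_classes = L,
         confusion = conf),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> ACC %.4f | MCC %.4f | macro F1 %.4f | weighted F1 %.4f\n",
              x$accuracy, x$mcc, x$macro_f1, x$weighted_f1))
  cat("per-class F1:",
      paste(sprintf("%s %.4f", names(x$per_class_f1), x$per_class_f1),
            collapse = ", "), "\n")
  invisible(x)
}

# one summary-table row (per-class F1s + ACC/MCC/macro/weighted F1)
eval_to_row <- function(ev) {
  out <- as.list(ev$per_class_f1)
  out$ACC <- ev$accuracy
  out$MCC <- ev$mcc
  out$macro_F1 <- ev$macro_f1
  out$weighted_F1 <- ev$weighted_f1
  as.data.frame(out, check.names = FALSE)
}
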