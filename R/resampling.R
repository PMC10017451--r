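#' SMOTE oversampling to the majority-class size
#'
#' Every class smaller than the largest is topped up with synthetic rows:
#' for each new row a minority sample `x` is drawn, one of its `k`
#' same-class Euclidean nearest neighbors `x_nn` is picked, and the
#' synthetic point is `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)` —
#' a random point on the open segment between the two. Original rows are
#' kept unchanged and first; synthetic rows are flagged. `k` is capped at
#' `class size - 1` with a warning when a class is too small to supply `k`
#' neighbors.
#'
#' @param X numeric matrix (rows = samples).
#' @param y class labels aligned with the rows of `X`.
#' @param k number of nearest neighbors considered (default 5).
#' @param seed integer seed.
#' @return a `balanced_set`: list with `values`, `labels` and logical
#'   `synthetic_flags` (TRUE for generated rows).
#' @export
smote_balance <- function(X, y, k = 5L, seed = 0L) {
  X <- as.matrix(X)
  if (k <= 0) stopf("k must be positive")
  y <- if (is.factor(y)) y else factor(y)
  if (length(y) != nrow(X)) stopf("labels must align with rows of X")
  counts <- table(y)
  target <- max(counts)
  deficits <- target - counts
  if (any(counts[deficits > 0] < 2L))
    stopf("class '%s' has fewer than 2 samples; SMOTE cannot interpolate",
          names(counts)[counts < 2L & deficits > 0][1])

  new_rows <- list()
  new_labels <- list()
  with_seed(seed, {
    for (cl in names(counts)[deficits > 0]) {
      idx <- which(y == cl)
      n_c <- length(idx)
      k_eff <- min(k, n_c - 1L)
      if (k_eff < k)
        warning(sprintf("class '%s': k reduced from %d to %d (class size %d)",
                        cl, k, k_eff, n_c), call. = FALSE)
      # k nearest same-class neighbors for every class member
      d <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
      diag(d) <- Inf
      nn <- apply(d, 1L, function(r) order(r)[seq_len(k_eff)])
      nn <- matrix(nn, nrow = k_eff)     # k_eff x n_c
      n_new <- deficits[[cl]]
      base <- sample.int(n_c, n_new, replace = TRUE)
      pick <- sample.int(k_eff, n_new, replace = TRUE)
      lambda <- stats::runif(n_new)
      a <- X[idx[base], , drop = FALSE]
      b <- X[idx[nn[cbind(pick, base)]], , drop = FALSE]
      new_rows[[cl]] <- a + lambda * (b - a)
      new_labels[[cl]] <- rep(cl, n_new)
    }
  })

  if (length(new_rows) > 0) {
    values <- rbind(X, do.call(rbind, unname(new_rows)))
    labels <- factor(c(as.character(y), unlist(unname(new_labels))),
                     levels = levels(y))
    flags <- c(rep(FALSE, nrow(X)), rep(TRUE, nrow(values) - nrow(X)))
  } else {
    values <- X
    labels <- y
    flags <- rep(FALSE, nrow(X))
  }
  rownames(values) <- NULL
  structure(list(values = values, labels = labels, synthetic_flags = flags),
            class = "balanced_set")
}
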