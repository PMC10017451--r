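# Independent oracles used to validate the package's own implementations.
# They share no code with the package paths they check.

# brute-force mutual information (nats): explicit double sum over the
# joint frequency table
mi_oracle <- function(x, y) {
  ux <- unique(x)
  uy <- unique(y)
  n <- length(x)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        px <- sum(x == a) / n
        py <- sum(y == b) / n
        total <- total + pxy * log(pxy / (px * py))
      }
    }
  }
  total
}

# exhaustive greedy mRMR (MID criterion) recomputing every MI from scratch
# with mi_oracle at every step; returns 1-based gene indices in order
mrmr_oracle <- function(disc_cols, labels, top_n) {
  p <- length(disc_cols)
  selected <- integer(0)
  for (step in seq_len(top_n)) {
    best <- -Inf
    best_j <- NA_integer_
    for (j in seq_len(p)) {
      if (j %in% selected) next
      rel <- mi_oracle(disc_cols[[j]], labels)
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s)
          mi_oracle(disc_cols[[j]], disc_cols[[s]]), numeric(1)))
      crit <- rel - red
      if (crit > best + 1e-12) {   # strict improvement; ties keep smaller j
        best <- crit
        best_j <- j
      }
    }
    selected <- c(selected, best_j)
  }
  selected
}

# confusion-matrix metrics oracle; MCC via the Gorodkin multiclass closed
# form (a different formula from the covariance form the package uses)
metrics_oracle <- function(y_true, y_pred) {
  classes <- sort(unique(as.character(y_true)))
  L <- length(classes)
  n <- length(y_true)
  C <- matrix(0, L, L, dimnames = list(classes, classes))
  for (i in seq_len(n))
    C[as.character(y_true)[i], as.character(y_pred)[i]] <-
      C[as.character(y_true)[i], as.character(y_pred)[i]] + 1
  prec <- rec <- f1 <- numeric(L)
  for (i in seq_len(L)) {
    tp <- C[i, i]
    prec[i] <- if (sum(C[, i]) > 0) tp / sum(C[, i]) else 0
    rec[i] <- if (sum(C[i, ]) > 0) tp / sum(C[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- rowSums(C) / n
  cc <- sum(diag(C))
  ss <- n
  pk <- colSums(C)
  tk <- rowSums(C)
  num <- cc * ss - sum(pk * tk)
  den <- sqrt(ss^2 - sum(pk^2)) * sqrt(ss^2 - sum(tk^2))
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = cc / n,
       macro_f1 = mean(f1),
       weighted_f1 = sum(w * f1),
       mcc = if (den > 0) num / den else 0)
}

# linear-scan feasibility oracle: smallest subset within delta of the best
# weighted F1, or NA if the optimum is small or nothing else qualifies
feasible_oracle <- function(sizes, wf1, delta, min_optimal_size) {
  opt <- which.max(wf1)
  if (sizes[opt] <= min_optimal_size) return(NA_integer_)
  for (i in order(sizes)) {
    if (wf1[i] >= wf1[opt] - delta) {
      if (i == opt) return(NA_integer_)
      return(i)
    }
  }
  NA_integer_
}

# build an ifs_curve skeleton from sizes + weighted F1s (for selector tests)
fake_curve <- function(sizes, wf1) {
  records <- Map(function(s, w)
    list(subset_size = s, classifier = "dt", eval = list(weighted_f1 = w)),
    sizes, wf1)
  structure(list(ranking_method = "mrmr", classifier = "dt",
                 records = records, step = 10L, cap = max(sizes),
                 folds = 10L, seed = 0L,
                 optimal_index = NA_integer_, feasible_index = NA_integer_),
            class = "ifs_curve")
}

# small labeled dataset with one clearly informative block of genes
tiny_dataset <- function(seed = 1, sizes = c(40, 60, 80), n_genes = 30,
                         n_informative = 4, effect = 2.5, dropout = 0.3) {
  generate_dataset(synth_spec(class_sizes = sizes, n_genes = n_genes,
                              n_informative = n_informative,
                              effect_size = effect, dropout_rate = dropout,
                              seed = seed,
                              class_names = sprintf("cls%d",
                                                    seq_along(sizes))))
}
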