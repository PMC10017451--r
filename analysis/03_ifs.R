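#!/usr/bin/env Rscript
# Stage 3: incremental feature selection over every (ranking, classifier)
# pair.
#
# Sweeps nested top-k subsets (step 10, up to 50 genes at this desk scale)
# of each stage-2 ranking, evaluating decision trees and random forests
# under stratified 10-fold CV with SMOTE-balanced training folds. Writes
# one curve TSV per pair and the optimal/feasible summary table under
# results/ifs/.

library(ifsrank)

seed <- 1L
cap <- 50L
data_dir <- "results/data"
rank_dir <- "results/rankings"
out <- "results/ifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_expression(file.path(data_dir, "matrix.mtx"), format = "mtx",
                      labels_path = file.path(data_dir, "labels.tsv"))
rankings <- lapply(list.files(rank_dir, full.names = TRUE), read_ranking)
names(rankings) <- vapply(rankings, `[[`, character(1), "method")

res <- run_matrix(ds, rankings, classifiers = c("dt", "rf"),
                  step = 10, cap = cap, folds = 10, seed = seed)
for (nm in names(res$curves))
  write_curve(res$curves[[nm]], file.path(out, paste0(nm, ".tsv")))
ifsrank:::write_table_lf(res$summary, file.path(out, "summary.tsv"))

print(res$summary, digits = 3)
rf_rows <- grepl("^rf", res$summary$classifier)
dt_rows <- grepl("^dt", res$summary$classifier)
cat(sprintf("\nbest RF weighted F1: %.3f | best DT weighted F1: %.3f\n",
            max(res$summary$weighted_F1[rf_rows]),
            max(res$summary$weighted_F1[dt_rows])))
cat("curves and summary written to", out, "\n")
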