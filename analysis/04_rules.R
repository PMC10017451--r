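#!/usr/bin/env Rscript
# Stage 4: mine if-then classification rules from each optimal decision
# tree.
#
# For every ranking, takes the optimal DT subset found in stage 3,
# retrains a full-depth CART tree on the SMOTE-balanced dataset restricted
# to those genes, and writes the root-to-leaf rules (TSV + readable text)
# and the per-class rule counts under results/rules/.

library(ifsrank)

seed <- 1L
data_dir <- "results/data"
rank_dir <- "results/rankings"
ifs_dir <- "results/ifs"
out <- "results/rules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_expression(file.path(data_dir, "matrix.mtx"), format = "mtx",
                      labels_path = file.path(data_dir, "labels.tsv"))
summary_tab <- read.delim(file.path(ifs_dir, "summary.tsv"))

counts <- list()
for (path in list.files(rank_dir, full.names = TRUE)) {
  rk <- read_ranking(path)
  row <- summary_tab[summary_tab$ranking == rk$method &
                       summary_tab$classifier == "dt", ]
  size <- row$n_features[1]
  mined <- mine_rules(ds, rk, subset_size = size, seed = seed)
  rs <- mined$rule_set
  write_rules(rs, file.path(out, paste0(rk$method, ".tsv")))
  writeLines(format_rules(rs), file.path(out, paste0(rk$method, ".txt")))
  counts[[rk$method]] <- c(as.integer(rs$class_counts),
                           total = length(rs$rules))
  cat(sprintf("%-10s %d genes -> %d rules (%s)\n", rk$method, size,
              length(rs$rules),
              paste(names(rs$class_counts), rs$class_counts,
                    collapse = ", ", sep = ": ")))
}
count_tab <- data.frame(ranking = names(counts),
                        do.call(rbind, counts), check.names = FALSE)
ifsrank:::write_table_lf(count_tab, file.path(out, "rule_counts.tsv"))
cat("rules written to", out, "\n")
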