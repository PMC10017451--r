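#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# Generates the default synthetic cohort: three vaccination-strategy
# classes of 300/600/900 cells over 500 genes, 10 of which are planted
# discriminative genes (class-specific up/neutral/down shifts of 2 log
# units), with 50% dropout. Writes the dataset in CellRanger-style MTX
# layout plus the ground-truth gene list under results/data/.

library(ifsrank)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synth_spec(seed = seed)
gen <- generate_dataset(spec)
print(gen$dataset)

write_expression(gen$dataset, out, format = "mtx")
writeLines(gen$truth$informative_genes, file.path(out, "planted_genes.txt"))

cat(sprintf("planted %d informative genes among %d: %s ...\n",
            length(gen$truth$informative_genes), ncol(gen$dataset$values),
            paste(head(gen$truth$informative_genes, 5), collapse = ", ")))
cat("dataset written to", out, "\n")
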