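#!/usr/bin/env Rscript
# Stage 5: intersect the five selected gene sets.
#
# For each ranking, takes the genes of the feasible RF classifier when one
# exists, otherwise of the optimal RF classifier, and decomposes the five
# sets into their Venn membership regions. Writes the per-gene membership
# table and region counts under results/consensus/.

library(ifsrank)

rank_dir <- "results/rankings"
ifs_dir <- "results/ifs"
out <- "results/consensus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

summary_tab <- read.delim(file.path(ifs_dir, "summary.tsv"))
sets <- list()
for (path in list.files(rank_dir, full.names = TRUE)) {
  rk <- read_ranking(path)
  rows <- summary_tab[summary_tab$ranking == rk$method, ]
  pick <- if (any(rows$classifier == "rf*")) "rf*" else "rf"
  size <- rows$n_features[rows$classifier == pick][1]
  sets[[rk$method]] <- rk$ordered_genes[seq_len(size)]
  cat(sprintf("%-10s %s set: %d genes\n", rk$method,
              if (pick == "rf*") "feasible" else "optimal", size))
}

rep <- venn_intersections(sets)
print(rep)
write_consensus(rep, file.path(out, "membership.tsv"),
                file.path(out, "regions.tsv"))
consensus_genes <- rep$membership$gene[rep$membership$consensus]
cat(sprintf("%d genes supported by >= %d methods: %s\n",
            length(consensus_genes), rep$consensus_min,
            paste(head(consensus_genes, 12), collapse = ", ")))
cat("consensus written to", out, "\n")
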