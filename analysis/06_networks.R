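#!/usr/bin/env Rscript
# Consensus correlation networks per treatment arm x stress phase: Pearson,
# Spearman and Kendall on CLR values, BH-FDR per measure, and only edges
# supported by at least two sign-consistent measures retained. The summary
# contrasts edge counts and the positive-edge share between arms.

suppressMessages(library(robustbiome))
tb <- read.delim("results/clr.tsv", check.names = FALSE)
clr <- as.matrix(tb[, -1]); rownames(clr) <- tb$sample_id
meta <- read.csv("results/data/metadata.csv")
meta <- meta[match(rownames(clr), meta$sample_id), ]

edges <- networks_by_stratum(clr, meta, group = "arm_phase")
summ <- network_summary(edges)
write.table(edges, "results/edges.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summ, "results/network_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in seq_len(nrow(summ)))
  cat(sprintf("%-10s %3d edges (%d positive / %d negative, %.0f%% positive)\n",
              summ$stratum[i], summ$n_edges[i], summ$n_positive[i],
              summ$n_negative[i], summ$percent_positive[i]))
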