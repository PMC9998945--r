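#!/usr/bin/env Rscript
# Functional potential: accumulate per-genome CAZy family counts over the
# microbes detected in each sample, then push the sample x family table
# through the same CLR -> delta -> gap-statistic clustering machinery used
# for species, summarizing arm trajectories across the functional clusters.

suppressMessages(library(robustbiome))
counts <- read_count_table("results/data/counts.tsv")
meta <- read.csv("results/data/metadata.csv")
meta <- meta[match(rownames(counts), meta$sample_id), ]
profiles <- load_cazy_profiles("results/data/cazy_profiles.tsv")

cz <- accumulate_cazy(profiles, counts, mode = "presence")
write.table(data.frame(sample_id = rownames(cz), cz, check.names = FALSE),
            "results/cazy_sample.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

nz <- colSums(cz) > 0
clr <- clr_transform(impute_zeros(cz[, nz, drop = FALSE]))
delta <- delta_clr(clr, meta)
g <- gap_statistic(delta, kind = "aitchison_euclidean", k_max = 7, B = 50, seed = 7)
sol <- g$solutions[[g$chosen_k]]
occ <- cluster_occupancy(sol, meta)
write.table(occ, "results/cazy_occupancy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

classes <- sub("[0-9]+$", "", colnames(cz))
cat(sprintf("CAZy table: %d families (%s)\n", ncol(cz),
            paste(sprintf("%s x%d", names(table(classes)), table(classes)),
                  collapse = ", ")))
cat(sprintf("functional clustering: gap chooses k = %d sample clusters\n",
            g$chosen_k))
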