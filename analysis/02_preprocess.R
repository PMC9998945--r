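#!/usr/bin/env Rscript
# Compositional preprocessing: prevalence/abundance filtering per stress
# phase (superset of the pre- and post-stress passing sets), rarefaction to
# the minimum depth for diversity work, and Bayesian-multiplicative zero
# replacement followed by the CLR transform for everything downstream.

suppressMessages(library(robustbiome))
counts <- read_count_table("results/data/counts.tsv")
meta <- read.csv("results/data/metadata.csv")

ts <- prevalence_abundance_filter(counts, meta$phase,
                                  prevalence = 0.75, min_relabund = 1e-5)
write.table(ts$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rarefied <- rarefy_counts(counts, seed = 3)
write_count_table(rarefied, "results/rarefied.tsv")

clr <- clr_transform(impute_zeros(counts[, ts$superset, drop = FALSE]))
write.table(data.frame(sample_id = rownames(clr), clr, check.names = FALSE),
            "results/clr.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("filter: %d pre-phase, %d post-phase, %d superset taxa; rarefied to %s reads\n",
            length(ts$pre_set), length(ts$post_set), length(ts$superset),
            format(min(rowSums(counts)), big.mark = ",")))
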