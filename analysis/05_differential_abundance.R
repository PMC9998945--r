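#!/usr/bin/env Rscript
# Differential abundance: per-species mixed models on CLR values with the
# compositional bias removed (mode of the coefficient distribution across
# species), then day-0-anchored treated-vs-control log2 fold changes per
# timepoint with BH-FDR across species within each timepoint.

suppressMessages(library(robustbiome))
tb <- read.delim("results/clr.tsv", check.names = FALSE)
clr <- as.matrix(tb[, -1]); rownames(clr) <- tb$sample_id
meta <- read.csv("results/data/metadata.csv")
meta <- meta[match(rownames(clr), meta$sample_id), ]

fits <- fit_linda(clr, meta)
fc <- baseline_fold_changes(fits)
write.table(fc, "results/fold_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ia <- grep("^treatment.*:timepoint", colnames(fits$coef_raw), value = TRUE)
cat(sprintf("compositional bias removed per covariate: %s\n",
            paste(sprintf("%s %+0.2f", sub(".*timepoint", "", ia),
                          fits$bias[ia]), collapse = ", ")))
for (tp in unique(fc$timepoint))
  cat(sprintf("%-4s: %2d species significant (BH < 0.05)\n", tp,
              sum(fc$p_adj[fc$timepoint == tp] < 0.05)))
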