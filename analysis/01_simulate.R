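#!/usr/bin/env Rscript
# Simulate the study: 20 horses in two arms (Control vs SCFP-supplemented),
# fecal samples at d0/d28/d56 pre-stress and h0/h12/h24/h72 post-stress,
# 30 species at ~390k reads/sample. The stressor raises one species block
# and lowers another; the treated arm receives a damped version. Ground
# truth (expected CLR shifts, planted correlations, cluster labels) is
# stored alongside the data so later steps can be scored against it.

suppressMessages(library(robustbiome))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()           # the study conditions; see ?sim_config
study <- generate_study(cfg, seed = 1)
profiles <- generate_cazy_profiles(cfg, seed = 2,
                                   taxon_groups = study$truth$taxon_cluster)

write_count_table(study$counts, "results/data/counts.tsv")
write.csv(study$metadata, "results/data/metadata.csv", row.names = FALSE)
jsonlite::write_json(list(taxon_cluster = as.list(study$truth$taxon_cluster),
                          sample_cluster = as.list(study$truth$sample_cluster)),
                     "results/data/truth.json", auto_unbox = TRUE)
write.table(data.frame(taxon = rownames(profiles), profiles, check.names = FALSE),
            "results/data/cazy_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("simulated %d samples x %d species; depths %s-%s reads\n",
            nrow(study$counts), ncol(study$counts),
            format(min(rowSums(study$counts)), big.mark = ","),
            format(max(rowSums(study$counts)), big.mark = ",")))
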