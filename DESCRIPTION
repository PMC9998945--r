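Package: robustbiome
Title: Compositional Robustness Analysis of Longitudinal Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the robustness of a gut microbial community
    to an acute stressor in longitudinal, repeated-measures study designs.
    Implements compositional preprocessing (Bayesian-multiplicative zero
    replacement, centered log-ratio transform, Aitchison distances,
    rarefaction, prevalence/abundance filtering), Shannon alpha-diversity
    mixed models with treatment-by-timepoint contrasts, permutational
    multivariate ANOVA on distance matrices with sequential sums of squares,
    bias-corrected per-taxon differential abundance with day-0 baseline fold
    changes, consensus correlation networks combining Pearson, Spearman and
    Kendall measures, gap-statistic k-medoids clustering of delta-CLR
    profiles, and accumulation of carbohydrate-active enzyme (CAZy) family
    potential per sample. A synthetic-study generator with known ground truth
    emulates a two-arm, seven-timepoint equine stress-challenge design so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster
Config/testthat/edition: 3
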