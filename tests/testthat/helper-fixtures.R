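# small study configurations used across tests
tiny_config <- function(...) {
  defaults <- list(n_subjects_per_arm = 4L, n_taxa = 12L, mean_depth = 20000,
                   depth_cv = 0.2, subject_sd = 0.2, noise_sd = 0.3,
                   stress_up_taxa = 1:5, stress_down_taxa = 6:8,
                   stress_effect = 2, treatment_attenuation = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# random compositions for metric / invariance checks
random_compositions <- function(n, d, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * d) + 1e-3, n, d)
  m / rowSums(m)
}

# CLR-scale study simulated directly (no counting noise): per-taxon mixed
# model ground truth for differential-abundance tests
simulate_clr_study <- function(n_per_arm = 10, n_taxa = 30, spike_taxa = integer(0),
                               spike_log_shift = 0, subject_sd = 0.2,
                               noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(2 * n_per_arm))
  arm <- rep(c("CON", "SCFP"), each = n_per_arm)
  meta <- expand.grid(subject_id = subjects, timepoint = c("d0", "h0"),
                      stringsAsFactors = FALSE)
  meta$treatment <- arm[match(meta$subject_id, subjects)]
  meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = "_")
  lam <- matrix(rnorm(nrow(meta) * n_taxa, 0, noise_sd), nrow(meta), n_taxa)
  lam <- lam + rnorm(length(subjects), 0, subject_sd)[match(meta$subject_id, subjects)]
  post_trt <- meta$timepoint == "h0" & meta$treatment == "SCFP"
  lam[post_trt, spike_taxa] <- lam[post_trt, spike_taxa] + spike_log_shift
  clr <- lam - rowMeans(lam)
  colnames(clr) <- sprintf("sp%02d", seq_len(n_taxa))
  rownames(clr) <- meta$sample_id
  list(clr = clr, meta = meta,
       # CLR-scale interaction truth (closure spreads the spike over all taxa)
       clr_effect = {
         d <- numeric(n_taxa); d[spike_taxa] <- spike_log_shift
         d - mean(d)
       },
       # absolute log-abundance truth: what the bias-corrected coefficient targets
       spike_log_shift = spike_log_shift)
}

# mean silhouette width of a 1-d embedding against known labels
silhouette_1d <- function(x, labels) {
  d <- as.matrix(dist(x))
  mean(vapply(seq_along(x), function(i) {
    a <- mean(d[i, setdiff(which(labels == labels[i]), i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}
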