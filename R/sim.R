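#' Configuration for a synthetic longitudinal stress-challenge study
#'
#' Builds the parameter set for [generate_study()]. The defaults emulate a
#' two-arm equine feeding trial with an acute stressor: 10 subjects per arm,
#' fecal samples at three pre-stress days (`d0`, `d28`, `d56`) and four
#' post-stress hours (`h0`, `h12`, `h24`, `h72`), 30 species, and shotgun
#' sequencing depth around 390k reads per sample with a coefficient of
#' variation of 0.3. The stress perturbation raises one block of species and
#' lowers another on the log-abundance (hence CLR) scale; the treated arm
#' receives an attenuated version of the same perturbation.
#'
#' @param n_subjects_per_arm subjects per treatment arm.
#' @param timepoints ordered timepoint labels.
#' @param phase_map named character vector mapping each timepoint to
#'   `"pre"` or `"post"` (stress).
#' @param n_taxa number of species.
#' @param mean_depth mean sequencing depth (reads/sample).
#' @param depth_cv coefficient of variation of the lognormal depth
#'   distribution; 0 gives a fixed depth.
#' @param baseline_logabund vector of length `n_taxa` of log-scale baseline
#'   abundances; default is a linear ramp from 4 to -4 (about a 3000-fold
#'   dynamic range, typical of a dominated gut community).
#' @param subject_sd standard deviation of subject-level random intercepts
#'   on the log scale.
#' @param noise_sd standard deviation of i.i.d. log-scale sample noise.
#' @param stress_up_taxa,stress_down_taxa disjoint taxon index sets pushed up
#'   resp. down by the stressor at post-stress timepoints.
#' @param stress_effect log-scale magnitude of the stress shift.
#' @param stress_decay optional numeric vector named by the post-stress
#'   timepoints multiplying `stress_effect` (per-timepoint decay); default
#'   constant 1.
#' @param treatment_attenuation fraction of the stress effect removed in the
#'   treated arm (0 = no protection, 1 = full protection).
#' @param planted_corr_pairs data frame with columns `i`, `j`, `loading`
#'   planting inter-taxon correlations through shared latent factors; the
#'   sign of `loading` sets the sign of the planted correlation. Default: 10
#'   positive and 2 negative couplings.
#' @param dropout_n number of randomly dropped samples (emulating samples
#'   lost to low sequencing throughput); default 0.
#' @param seed default RNG seed used by [generate_study()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_arm = 10L,
                       timepoints = c("d0", "d28", "d56", "h0", "h12", "h24", "h72"),
                       phase_map = c(d0 = "pre", d28 = "pre", d56 = "pre",
                                     h0 = "post", h12 = "post", h24 = "post", h72 = "post"),
                       n_taxa = 30L,
                       mean_depth = 389680L,
                       depth_cv = 0.3,
                       baseline_logabund = NULL,
                       subject_sd = 0.3,
                       noise_sd = 0.5,
                       stress_up_taxa = 1:18,
                       stress_down_taxa = 19:27,
                       stress_effect = 2,
                       stress_decay = NULL,
                       treatment_attenuation = 0.8,
                       planted_corr_pairs = NULL,
                       dropout_n = 0L,
                       seed = 1L) {
  if (is.null(baseline_logabund))
    baseline_logabund <- seq(4, -4, length.out = n_taxa)
  if (is.null(planted_corr_pairs)) {
    idx <- seq_len(min(24L, 2L * (n_taxa %/% 2L)))
    pr <- matrix(idx, ncol = 2L, byrow = TRUE)
    planted_corr_pairs <- data.frame(
      i = pr[, 1L], j = pr[, 2L],
      loading = c(rep(0.8, max(0L, nrow(pr) - 2L)), rep(-0.8, min(2L, nrow(pr))))
    )
  }
  cfg <- list(
    n_subjects_per_arm = as.integer(n_subjects_per_arm),
    timepoints = timepoints,
    phase_map = phase_map,
    n_taxa = as.integer(n_taxa),
    mean_depth = as.numeric(mean_depth),
    depth_cv = depth_cv,
    baseline_logabund = baseline_logabund,
    subject_sd = subject_sd,
    noise_sd = noise_sd,
    stress_up_taxa = as.integer(stress_up_taxa),
    stress_down_taxa = as.integer(stress_down_taxa),
    stress_effect = stress_effect,
    stress_decay = stress_decay,
    treatment_attenuation = treatment_attenuation,
    planted_corr_pairs = planted_corr_pairs,
    dropout_n = as.integer(dropout_n),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects_per_arm < 1L) stopf("invalid sim_config: n_subjects_per_arm must be >= 1")
  if (length(cfg$timepoints) < 2L || anyDuplicated(cfg$timepoints))
    stopf("invalid sim_config: timepoints must be >= 2 distinct labels")
  if (!all(cfg$timepoints %in% names(cfg$phase_map)))
    stopf("invalid sim_config: phase_map must cover every timepoint")
  if (!all(cfg$phase_map %in% c("pre", "post")))
    stopf("invalid sim_config: phase_map values must be 'pre' or 'post'")
  if (cfg$n_taxa < 2L) stopf("invalid sim_config: n_taxa must be >= 2")
  if (length(cfg$baseline_logabund) != cfg$n_taxa)
    stopf("invalid sim_config: baseline_logabund length must equal n_taxa")
  if (cfg$mean_depth <= 0) stopf("invalid sim_config: mean_depth must be positive")
  for (f in c("depth_cv", "subject_sd", "noise_sd", "stress_effect"))
    if (cfg[[f]] < 0) stopf("invalid sim_config: %s must be >= 0", f)
  if (length(intersect(cfg$stress_up_taxa, cfg$stress_down_taxa)) > 0L)
    stopf("invalid sim_config: stress_up_taxa and stress_down_taxa must be disjoint")
  if (length(cfg$stress_up_taxa) + length(cfg$stress_down_taxa) > cfg$n_taxa)
    stopf("invalid sim_config: n_taxa must be >= |stress_up_taxa| + |stress_down_taxa|")
  if (any(c(cfg$stress_up_taxa, cfg$stress_down_taxa) > cfg$n_taxa) ||
      any(c(cfg$stress_up_taxa, cfg$stress_down_taxa) < 1L))
    stopf("invalid sim_config: stress taxon indices out of range")
  if (cfg$treatment_attenuation < 0 || cfg$treatment_attenuation > 1)
    stopf("invalid sim_config: treatment_attenuation must be in [0, 1]")
  if (!is.null(cfg$stress_decay)) {
    post_tp <- cfg$timepoints[cfg$phase_map[cfg$timepoints] == "post"]
    if (!all(post_tp %in% names(cfg$stress_decay)))
      stopf("invalid sim_config: stress_decay must be named by all post-stress timepoints")
  }
  pcp <- cfg$planted_corr_pairs
  if (!is.data.frame(pcp) || !all(c("i", "j", "loading") %in% names(pcp)))
    stopf("invalid sim_config: planted_corr_pairs needs columns i, j, loading")
  if (nrow(pcp) && (any(pcp$i == pcp$j) || any(c(pcp$i, pcp$j) > cfg$n_taxa)))
    stopf("invalid sim_config: planted_corr_pairs indices invalid")
  if (cfg$dropout_n < 0L) stopf("invalid sim_config: dropout_n must be >= 0")
  invisible(cfg)
}

# log-scale stress shift per taxon for one arm at one timepoint
stress_shift <- function(cfg, arm, timepoint) {
  delta <- numeric(cfg$n_taxa)
  if (cfg$phase_map[[timepoint]] == "post") {
    eff <- cfg$stress_effect
    if (!is.null(cfg$stress_decay)) eff <- eff * cfg$stress_decay[[timepoint]]
    if (arm == "SCFP") eff <- eff * (1 - cfg$treatment_attenuation)
    delta[cfg$stress_up_taxa] <- eff
    delta[cfg$stress_down_taxa] <- -eff
  }
  delta
}

#' Simulate a two-arm longitudinal microbiome study with known ground truth
#'
#' Draws one sample per subject x timepoint from a logistic-normal
#' multinomial model: log-abundance = baseline + subject random intercept +
#' arm/phase stress shift + shared latent factors (planted correlations) +
#' i.i.d. Gaussian noise; counts are multinomial at a lognormally drawn
#' depth. Because CLR of a softmax equals the centered log-abundance, planted
#' effects translate exactly into expected CLR shifts, which are recorded in
#' the returned truth object.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical
#'   `(config, seed)` give identical output.
#' @return list with elements
#'   \describe{
#'     \item{counts}{integer matrix, samples x taxa.}
#'     \item{metadata}{data frame: `sample_id`, `subject_id`, `treatment`
#'       (`CON`/`SCFP`), `timepoint` (factor in design order), `phase`.}
#'     \item{truth}{list: `expected_clr_shift` (taxa x timepoints x arms
#'       array of CLR shifts vs day 0), `subject_intercepts`,
#'       `planted_corr_pairs`, `taxon_cluster` (`up`/`down`/`null`),
#'       `sample_cluster` (planted sample regime labels).}
#'   }
#' @export
generate_study <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  n_arm <- cfg$n_subjects_per_arm
  subjects <- sprintf("H%02d", seq_len(2L * n_arm))
  arms <- rep(c("CON", "SCFP"), each = n_arm)
  names(arms) <- subjects
  taxa <- sprintf("sp%02d", seq_len(cfg$n_taxa))

  meta <- expand.grid(subject_id = subjects, timepoint = cfg$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[order(match(meta$subject_id, subjects),
                     match(meta$timepoint, cfg$timepoints)), , drop = FALSE]
  meta$treatment <- arms[meta$subject_id]
  meta$phase <- unname(cfg$phase_map[meta$timepoint])
  meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = "_")
  rownames(meta) <- NULL
  n_samp <- nrow(meta)

  u <- stats::rnorm(length(subjects), 0, cfg$subject_sd)
  names(u) <- subjects

  lam <- matrix(rep(cfg$baseline_logabund, each = n_samp), n_samp, cfg$n_taxa)
  lam <- lam + u[meta$subject_id]
  for (r in seq_len(n_samp))
    lam[r, ] <- lam[r, ] + stress_shift(cfg, meta$treatment[r], meta$timepoint[r])
  pcp <- cfg$planted_corr_pairs
  if (nrow(pcp)) {
    z <- matrix(stats::rnorm(n_samp * nrow(pcp)), n_samp, nrow(pcp))
    for (q in seq_len(nrow(pcp))) {
      l <- pcp$loading[q]
      lam[, pcp$i[q]] <- lam[, pcp$i[q]] + abs(l) * z[, q]
      lam[, pcp$j[q]] <- lam[, pcp$j[q]] + l * z[, q]
    }
  }
  if (cfg$noise_sd > 0)
    lam <- lam + matrix(stats::rnorm(n_samp * cfg$n_taxa, 0, cfg$noise_sd), n_samp)

  probs <- softmax_rows(lam)
  if (cfg$depth_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$depth_cv^2))
    depths <- round(stats::rlnorm(n_samp, log(cfg$mean_depth) - sdlog^2 / 2, sdlog))
    depths <- pmax(depths, 1)
  } else depths <- rep(round(cfg$mean_depth), n_samp)

  counts <- matrix(0L, n_samp, cfg$n_taxa, dimnames = list(meta$sample_id, taxa))
  for (r in seq_len(n_samp))
    counts[r, ] <- as.integer(stats::rmultinom(1L, depths[r], probs[r, ]))

  if (cfg$dropout_n > 0L) {
    drop <- sample.int(n_samp, cfg$dropout_n)
    counts <- counts[-drop, , drop = FALSE]
    meta <- meta[-drop, , drop = FALSE]
  }
  meta$timepoint <- factor(meta$timepoint, levels = cfg$timepoints)
  meta$treatment <- factor(meta$treatment, levels = c("CON", "SCFP"))
  meta$phase <- factor(meta$phase, levels = c("pre", "post"))

  shift <- array(0, dim = c(cfg$n_taxa, length(cfg$timepoints), 2L),
                 dimnames = list(taxa, cfg$timepoints, c("CON", "SCFP")))
  for (arm in c("CON", "SCFP")) for (tp in cfg$timepoints) {
    d <- stress_shift(cfg, arm, tp)
    shift[, tp, arm] <- d - mean(d)  # CLR-scale shift vs the d0 baseline
  }
  taxon_cluster <- rep("null", cfg$n_taxa)
  taxon_cluster[cfg$stress_up_taxa] <- "up"
  taxon_cluster[cfg$stress_down_taxa] <- "down"
  names(taxon_cluster) <- taxa
  sample_cluster <- ifelse(meta$phase == "pre", "baseline",
                           ifelse(meta$treatment == "CON", "stressed", "treated_post"))
  names(sample_cluster) <- meta$sample_id

  truth <- list(expected_clr_shift = shift,
                subject_intercepts = u,
                planted_corr_pairs = pcp,
                taxon_cluster = taxon_cluster,
                sample_cluster = sample_cluster)
  list(counts = counts, metadata = meta, truth = truth)
}

#' Simulate per-taxon CAZy family profiles
#'
#' Generates a sparse taxa x CAZy-family count table (family names use the
#' six CAZy class prefixes AA, CBM, CE, GH, GT, PL). When `taxon_groups` is
#' supplied (e.g. the generator's planted up/down species clusters), each
#' group is enriched in its own block of families, so group-level abundance
#' shifts propagate into a two-regime functional signal.
#'
#' @param config a [sim_config()] (only `n_taxa` is used).
#' @param seed RNG seed.
#' @param n_families number of CAZy families.
#' @param sparsity probability that a taxon x family cell is zero
#'   (1 gives an all-zero table).
#' @param mean_count Poisson mean for non-zero cells.
#' @param taxon_groups optional character vector of length `n_taxa` of group
#'   labels used for block enrichment.
#' @param group_enrichment Poisson-mean multiplier of a group's own family
#'   block relative to the shared background.
#' @return integer matrix taxa x families.
#' @export
generate_cazy_profiles <- function(config, seed = config$seed, n_families = 40L,
                                   sparsity = 0.5, mean_count = 3,
                                   taxon_groups = NULL, group_enrichment = 4) {
  if (sparsity < 0 || sparsity > 1) stopf("sparsity must be in [0, 1]")
  set.seed(seed)
  n_taxa <- config$n_taxa
  prefixes <- c("AA", "CBM", "CE", "GH", "GT", "PL")
  fam <- character(0)
  num <- stats::setNames(rep(0L, length(prefixes)), prefixes)
  for (f in seq_len(n_families)) {
    p <- sample(prefixes, 1L)
    num[p] <- num[p] + 1L
    fam <- c(fam, paste0(p, num[p]))
  }
  taxa <- sprintf("sp%02d", seq_len(n_taxa))
  lam <- matrix(mean_count, n_taxa, n_families, dimnames = list(taxa, fam))
  if (!is.null(taxon_groups)) {
    if (length(taxon_groups) != n_taxa)
      stopf("taxon_groups must have length n_taxa")
    grp <- sort(unique(taxon_groups))
    blocks <- split(seq_len(n_families),
                    rep(seq_along(grp), length.out = n_families))
    for (g in seq_along(grp))
      lam[taxon_groups == grp[g], blocks[[g]]] <- mean_count * group_enrichment
  }
  m <- matrix(stats::rpois(n_taxa * n_families, as.vector(lam)), n_taxa, n_families,
              dimnames = list(taxa, fam))
  zero <- matrix(stats::runif(n_taxa * n_families) < sparsity, n_taxa, n_families)
  m[zero] <- 0L
  storage.mode(m) <- "integer"
  m
}
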