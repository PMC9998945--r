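pipeline_stages <- c("simulate", "preprocess", "diversity", "permanova",
                     "diffabund", "networks", "clustering", "cazy")

#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the synthetic-study (or input file) specification with every
#' numeric threshold the stages use, so no analysis constant is buried
#' inside a stage.
#'
#' @param sim a [sim_config()]; ignored when `counts_path`/`metadata_path`
#'   are given.
#' @param counts_path,metadata_path,cazy_path optional input files (taxa x
#'   sample TSV, metadata CSV, CAZy profile TSV) replacing simulation.
#' @param out_dir output directory for stage tables and the manifest.
#' @param prevalence,min_relabund taxon filter thresholds.
#' @param alpha significance level used for contrasts, fold changes and
#'   network edges.
#' @param min_support minimum supporting measures per network edge.
#' @param n_perm PERMANOVA permutations.
#' @param k_max,gap_B gap-statistic search range and reference count.
#' @param cazy_mode CAZy accumulation mode.
#' @param stages subset of stages to run (dependency order is enforced).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_path = NULL, metadata_path = NULL,
                            cazy_path = NULL,
                            out_dir = tempfile("robustbiome_run_"),
                            prevalence = 0.75, min_relabund = 1e-5,
                            alpha = 0.05, min_support = 2L,
                            n_perm = 999L, k_max = 7L, gap_B = 50L,
                            cazy_mode = "presence",
                            stages = pipeline_stages,
                            seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1, min_relabund >= 0,
            alpha > 0, alpha < 1, min_support >= 1, n_perm >= 99, k_max >= 2,
            gap_B >= 10)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- list(sim = sim, counts_path = counts_path,
              metadata_path = metadata_path, cazy_path = cazy_path,
              out_dir = out_dir, prevalence = prevalence,
              min_relabund = min_relabund, alpha = alpha,
              min_support = as.integer(min_support), n_perm = as.integer(n_perm),
              k_max = as.integer(k_max), gap_B = as.integer(gap_B),
              cazy_mode = cazy_mode,
              stages = pipeline_stages[pipeline_stages %in% stages],
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(cfg, offset) (cfg$seed * 101L + offset) %% .Machine$integer.max

#' Run the full robustness analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' compositional preprocessing, alpha/beta diversity, PERMANOVA,
#' differential abundance, consensus networks, delta-CLR clustering and
#' CAZy functional potential — writing each stage's tables under
#' `config$out_dir` and returning a manifest with seeds, output paths and
#' file hashes. Identical configs reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config")) stopf("config must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  state <- new.env(parent = emptyenv())
  add_out <- function(stage, name, path) {
    outputs[[stage]] <<- c(outputs[[stage]], stats::setNames(path, name))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  p <- function(f) file.path(cfg$out_dir, f)

  ## -- simulate / load ------------------------------------------------
  run_stage("simulate", function() {
    if (is.null(cfg$counts_path)) {
      study <- generate_study(cfg$sim, seed = stage_seed(cfg, 1L))
      state$cazy_profiles <- generate_cazy_profiles(
        cfg$sim, seed = stage_seed(cfg, 2L),
        taxon_groups = study$truth$taxon_cluster)
      state$counts <- study$counts
      state$meta <- study$metadata
      state$truth <- study$truth
      jsonlite::write_json(list(taxon_cluster = as.list(study$truth$taxon_cluster),
                                sample_cluster = as.list(study$truth$sample_cluster)),
                           p("truth.json"), auto_unbox = TRUE)
      yaml::write_yaml(unclass(cfg$sim)[c("n_subjects_per_arm", "n_taxa",
                                          "mean_depth", "depth_cv", "subject_sd",
                                          "noise_sd", "stress_effect",
                                          "treatment_attenuation", "seed")],
                       p("sim_config.yaml"))
      add_out("simulate", "truth", p("truth.json"))
      add_out("simulate", "sim_config", p("sim_config.yaml"))
    } else {
      state$counts <- read_count_table(cfg$counts_path)
      state$meta <- utils::read.csv(cfg$metadata_path, stringsAsFactors = FALSE)
      state$cazy_profiles <- if (!is.null(cfg$cazy_path))
        load_cazy_profiles(cfg$cazy_path) else NULL
    }
    write_count_table(state$counts, p("counts.tsv"))
    utils::write.csv(state$meta, p("metadata.csv"), row.names = FALSE)
    add_out("simulate", "counts", p("counts.tsv"))
    add_out("simulate", "metadata", p("metadata.csv"))
  })

  ## -- preprocess -----------------------------------------------------
  run_stage("preprocess", function() {
    ts <- prevalence_abundance_filter(state$counts, state$meta$phase,
                                      prevalence = cfg$prevalence,
                                      min_relabund = cfg$min_relabund)
    state$taxon_set <- ts
    write_tsv(ts$report, p("filter_report.tsv"))
    state$rarefied <- rarefy_counts(state$counts, seed = stage_seed(cfg, 3L))
    filtered <- state$counts[, ts$superset, drop = FALSE]
    state$clr <- clr_transform(impute_zeros(filtered))
    write_tsv(data.frame(sample_id = rownames(state$clr), state$clr,
                         check.names = FALSE), p("clr.tsv"))
    add_out("preprocess", "filter_report", p("filter_report.tsv"))
    add_out("preprocess", "clr", p("clr.tsv"))
  })

  ## -- diversity ------------------------------------------------------
  run_stage("diversity", function() {
    keep <- rownames(state$rarefied)
    meta_r <- state$meta[match(keep, state$meta$sample_id), , drop = FALSE]
    H <- shannon_index(state$rarefied)
    state$shannon <- H
    state$meta_rarefied <- meta_r
    write_tsv(data.frame(sample_id = names(H), shannon = H), p("shannon.tsv"))
    fit <- fit_alpha_model(H, meta_r)
    state$alpha_fit <- fit
    jsonlite::write_json(list(fixef = as.list(fit$fixef),
                              subject_sd = fit$subject_sd,
                              residual_sd = fit$residual_sd),
                         p("alpha_model.json"), auto_unbox = TRUE, digits = NA)
    cw <- alpha_contrasts(fit, "within_group_pairwise")
    cb <- alpha_contrasts(fit, "between_group_per_timepoint")
    state$contrasts_within <- cw
    state$contrasts_between <- cb
    write_tsv(cw, p("alpha_contrasts_within.tsv"))
    write_tsv(cb, p("alpha_contrasts_between.tsv"))
    ord <- pca_ordination(state$clr)
    write_tsv(data.frame(sample_id = rownames(ord$scores),
                         ord$scores[, 1:min(5, ncol(ord$scores))],
                         check.names = FALSE), p("pca_scores.tsv"))
    add_out("diversity", "shannon", p("shannon.tsv"))
    add_out("diversity", "alpha_model", p("alpha_model.json"))
    add_out("diversity", "contrasts_within", p("alpha_contrasts_within.tsv"))
    add_out("diversity", "contrasts_between", p("alpha_contrasts_between.tsv"))
    add_out("diversity", "pca_scores", p("pca_scores.tsv"))
  })

  ## -- permanova ------------------------------------------------------
  run_stage("permanova", function() {
    d <- aitchison_dist(state$clr)
    res <- permanova(d, state$meta,
                     terms = c("treatment", "timepoint", "treatment:timepoint"),
                     n_perm = cfg$n_perm, seed = stage_seed(cfg, 4L))
    state$permanova <- res
    out <- cbind(res, n_perm = attr(res, "n_perm"), seed = attr(res, "seed"))
    write_tsv(out, p("permanova.tsv"))
    add_out("permanova", "permanova", p("permanova.tsv"))
  })

  ## -- differential abundance -----------------------------------------
  run_stage("diffabund", function() {
    fits <- fit_linda(state$clr, state$meta)
    fc <- baseline_fold_changes(fits, alpha = cfg$alpha)
    state$fold_changes <- fc
    write_tsv(fc, p("fold_changes.tsv"))
    add_out("diffabund", "fold_changes", p("fold_changes.tsv"))
  })

  ## -- networks -------------------------------------------------------
  run_stage("networks", function() {
    edges <- networks_by_stratum(state$clr, state$meta,
                                 alpha = cfg$alpha, min_support = cfg$min_support)
    state$edges <- edges
    state$network_summary <- network_summary(edges)
    write_tsv(edges, p("edges.tsv"))
    write_tsv(state$network_summary, p("network_summary.tsv"))
    add_out("networks", "edges", p("edges.tsv"))
    add_out("networks", "network_summary", p("network_summary.tsv"))
  })

  ## -- clustering -----------------------------------------------------
  run_stage("clustering", function() {
    delta <- delta_clr(state$clr, state$meta)
    state$delta <- delta
    gs <- gap_statistic(t(delta), kind = "spearman",
                        k_max = min(cfg$k_max, ncol(delta) - 1L),
                        B = cfg$gap_B, seed = stage_seed(cfg, 5L))
    state$species_gap <- gs
    sp_sol <- gs$solutions[[gs$chosen_k]]
    state$species_clusters <- sp_sol
    write_tsv(gs$table, p("species_gap.tsv"))
    write_tsv(data.frame(item = names(sp_sol$clustering),
                         cluster = sp_sol$clustering), p("species_clusters.tsv"))
    gsam <- gap_statistic(delta, kind = "aitchison_euclidean",
                          k_max = cfg$k_max, B = cfg$gap_B,
                          seed = stage_seed(cfg, 6L))
    state$sample_gap <- gsam
    sam_sol <- gsam$solutions[[gsam$chosen_k]]
    state$sample_clusters <- sam_sol
    meta_d <- state$meta[match(rownames(delta), state$meta$sample_id), ]
    occ <- cluster_occupancy(sam_sol, meta_d)
    state$occupancy <- occ
    write_tsv(data.frame(item = names(sam_sol$clustering),
                         cluster = sam_sol$clustering), p("sample_clusters.tsv"))
    write_tsv(occ, p("sample_occupancy.tsv"))
    add_out("clustering", "species_gap", p("species_gap.tsv"))
    add_out("clustering", "species_clusters", p("species_clusters.tsv"))
    add_out("clustering", "sample_clusters", p("sample_clusters.tsv"))
    add_out("clustering", "sample_occupancy", p("sample_occupancy.tsv"))
  })

  ## -- cazy -----------------------------------------------------------
  run_stage("cazy", function() {
    if (is.null(state$cazy_profiles)) return(invisible(NULL))
    cz <- accumulate_cazy(state$cazy_profiles, state$counts, mode = cfg$cazy_mode)
    state$cazy_sample <- cz
    write_tsv(data.frame(sample_id = rownames(cz), cz, check.names = FALSE),
              p("cazy_sample.tsv"))
    nz <- colSums(cz) > 0
    cz_clr <- clr_transform(impute_zeros(round(cz[, nz, drop = FALSE])))
    cz_delta <- delta_clr(cz_clr, state$meta)
    gc <- gap_statistic(cz_delta, kind = "aitchison_euclidean",
                        k_max = cfg$k_max, B = cfg$gap_B,
                        seed = stage_seed(cfg, 7L))
    state$cazy_gap <- gc
    cz_sol <- gc$solutions[[gc$chosen_k]]
    meta_d <- state$meta[match(rownames(cz_delta), state$meta$sample_id), ]
    occ <- cluster_occupancy(cz_sol, meta_d)
    state$cazy_occupancy <- occ
    write_tsv(data.frame(item = names(cz_sol$clustering),
                         cluster = cz_sol$clustering), p("cazy_clusters.tsv"))
    write_tsv(occ, p("cazy_occupancy.tsv"))
    add_out("cazy", "cazy_sample", p("cazy_sample.tsv"))
    add_out("cazy", "cazy_clusters", p("cazy_clusters.tsv"))
    add_out("cazy", "cazy_occupancy", p("cazy_occupancy.tsv"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("robustbiome")),
    seed = cfg$seed,
    stages = cfg$stages,
    thresholds = cfg[c("prevalence", "min_relabund", "alpha", "min_support",
                       "n_perm", "k_max", "gap_B", "cazy_mode")],
    outputs = lapply(outputs, function(o) as.list(o)),
    hashes = as.list(tools::md5sum(unlist(outputs, use.names = FALSE)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- list(manifest = manifest, state = state)
  class(res) <- "run_manifest"
  invisible(res)
}
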