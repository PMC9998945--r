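#' Shannon diversity index per sample
#'
#' `H = -sum_i p_i ln p_i` over taxa with positive counts (natural log).
#'
#' @param counts samples x taxa matrix.
#' @return named numeric vector of H values.
#' @export
shannon_index <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0] %||% which(totals == 0)
    stopf("empty sample(s): %s", paste(bad, collapse = ", "))
  }
  p <- counts / totals
  apply(p, 1L, function(pi) { pi <- pi[pi > 0]; -sum(pi * log(pi)) })
}

#' Mixed-effects model for alpha diversity
#'
#' Fits `H ~ treatment * time + (1 | subject)` by REML, the standard
#' longitudinal model for within-sample diversity with subject (horse) as a
#' random intercept. `time_term = "timepoint"` uses the full timepoint
#' factor; `"phase"` replaces it with the binary pre/post stress factor (the
#' stress-only model, since stress is nested within timepoint).
#'
#' @param H per-sample Shannon values, named by sample id or aligned with
#'   `meta` rows.
#' @param meta data frame with columns `sample_id`, `subject_id`,
#'   `treatment`, `timepoint`, `phase`.
#' @param time_term `"timepoint"` (default) or `"phase"`.
#' @return object of class `alpha_fit`: the `lmerTest` model plus extracted
#'   fixed effects, variance components and fitted values.
#' @export
fit_alpha_model <- function(H, meta, time_term = c("timepoint", "phase")) {
  time_term <- match.arg(time_term)
  if (!is.null(names(H))) {
    miss <- setdiff(meta$sample_id, names(H))
    if (length(miss)) stopf("H missing for sample(s): %s", paste(miss, collapse = ", "))
    meta <- meta[meta$sample_id %in% names(H), , drop = FALSE]
    H <- H[meta$sample_id]
  } else if (length(H) != nrow(meta)) {
    stopf("H must be named by sample id or aligned with meta rows")
  }
  d <- data.frame(H = as.numeric(H),
                  treatment = factor(meta$treatment),
                  time = factor(meta[[time_term]]),
                  subject = factor(meta$subject_id))
  if (nlevels(d$treatment) < 2L || nlevels(d$time) < 2L)
    stopf("treatment and %s need at least two levels each", time_term)
  X <- stats::model.matrix(~ treatment * time, d)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[-seq_len(qr(X)$rank)]
    stopf("singular fixed-effect design; aliased term(s): %s",
          paste(ali, collapse = ", "))
  }
  fit <- suppressMessages(lmerTest::lmer(
    H ~ treatment * time + (1 | subject), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    model = fit,
    data = d,
    time_term = time_term,
    fixef = lme4::fixef(fit),
    subject_sd = vc$sdcor[vc$grp == "subject"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    fitted = stats::fitted(fit)
  )
  class(out) <- "alpha_fit"
  out
}

#' Treatment / timepoint contrasts on an alpha-diversity fit
#'
#' `within_group_pairwise` compares all timepoint pairs inside each arm
#' (21 pairs per arm for 7 timepoints), Bonferroni-adjusted over the pairs
#' tested within the family; `between_group_per_timepoint` tests treated vs
#' control at each timepoint. Degrees of freedom use the Satterthwaite
#' approximation.
#'
#' @param fit an `alpha_fit`.
#' @param scheme contrast scheme (see above).
#' @param family `"per_group"` (default) adjusts within each arm
#'   (resp. over the per-timepoint tests); `"pooled"` adjusts over all
#'   contrasts of the scheme jointly.
#' @return data frame of class `contrast_table`: contrast, group, estimate,
#'   SE, df, p_raw, p_adj, and significance flags at 0.05 / 0.01.
#' @export
alpha_contrasts <- function(fit,
                            scheme = c("within_group_pairwise",
                                       "between_group_per_timepoint"),
                            family = c("per_group", "pooled")) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  if (!inherits(fit, "alpha_fit")) stopf("fit must be an alpha_fit")
  if (scheme == "within_group_pairwise") {
    emm <- emmeans::emmeans(fit$model, ~ time | treatment,
                            lmer.df = "satterthwaite")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    grp <- as.character(prs$treatment)
  } else {
    emm <- emmeans::emmeans(fit$model, ~ treatment | time,
                            lmer.df = "satterthwaite")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    grp <- as.character(prs$time)
  }
  out <- data.frame(
    contrast = as.character(prs$contrast),
    group = grp,
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    p_raw = prs$p.value,
    stringsAsFactors = FALSE
  )
  if (family == "per_group") {
    out$p_adj <- stats::ave(out$p_raw, out$group,
                            FUN = function(p) pmin(1, p * length(p)))
  } else {
    out$p_adj <- pmin(1, out$p_raw * nrow(out))
  }
  out$adjustment <- "bonferroni"
  out$sig_05 <- out$p_adj < 0.05
  out$sig_01 <- out$p_adj < 0.01
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' PCA ordination of CLR data
#'
#' Column-centered principal component analysis of a CLR matrix; on CLR data
#' the inter-sample score distances reproduce Aitchison distances.
#'
#' @param clr samples x features CLR matrix.
#' @return list of class `pca_ordination`: `scores`, `loadings`,
#'   `var_explained` (non-increasing fractions summing to <= 1), `center`.
#' @export
pca_ordination <- function(clr) {
  if (!is.matrix(clr)) clr <- as.matrix(clr)
  if (nrow(clr) < 2L) stopf("need at least 2 samples")
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x, loadings = pc$rotation,
              var_explained = ve, center = pc$center)
  class(out) <- "pca_ordination"
  out
}
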