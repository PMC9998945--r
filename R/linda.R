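kde_mode <- function(x) {
  # Gaussian kernel, Silverman's rule-of-thumb bandwidth, 512-point grid
  if (length(unique(x)) == 1L) return(x[1])
  dd <- stats::density(x, bw = "nrd0", kernel = "gaussian", n = 512L)
  dd$x[which.max(dd$y)]
}

kde_mode_se <- function(x, n_boot = 200L) {
  # bootstrap SD of the mode estimator, on a private RNG stream so callers'
  # seeds are untouched
  if (length(unique(x)) == 1L) return(0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(19680808L)
  stats::sd(replicate(n_boot, kde_mode(sample(x, replace = TRUE))))
}

#' Bias-corrected per-taxon mixed linear models on CLR data
#'
#' Fits, for every taxon, the mixed model
#' `clr ~ treatment * timepoint + (1 | subject)` and then removes the common
#' compositional bias from every covariate's coefficients: because CLR
#' values are constrained to sum to zero across taxa, a true shift in a few
#' taxa induces an equal-and-opposite artefactual shift spread over all
#' taxa. Assuming most taxa are null for a given covariate, that bias is the
#' mode of the coefficient distribution across taxa (Gaussian kernel density
#' argmax) and is subtracted from each taxon's coefficient before Wald
#' testing.
#'
#' Subjects without a baseline-timepoint sample are excluded with a warning
#' (their day-0 anchored contrasts are undefined).
#'
#' @param clr samples x taxa CLR matrix (typically restricted to the filter
#'   superset).
#' @param meta per-sample design data frame (`sample_id`, `subject_id`,
#'   `treatment`, `timepoint`).
#' @param baseline baseline timepoint label (default `"d0"`).
#' @return object of class `linda_fit`: matrices of raw and corrected
#'   coefficients, model standard errors (`se`) and bias-uncertainty-inflated
#'   standard errors (`se_corrected`), per-covariate `bias` and its bootstrap
#'   `bias_se`, per-taxon random intercept SDs, Wald-type p-values from the
#'   corrected coefficients, and the factor level bookkeeping needed for
#'   contrasts.

#' @details With tens (rather than hundreds) of taxa, the mode estimate of
#'   the compositional bias is itself noticeably noisy; its bootstrap
#'   standard deviation is therefore added in quadrature to each model SE
#'   before testing, and t quantiles (df = observations minus fixed-effect
#'   parameters) replace normal ones.
#' @export
fit_linda <- function(clr, meta, baseline = "d0") {
  if (!is.matrix(clr)) clr <- as.matrix(clr)
  if (ncol(clr) < 5L)
    stopf("fit_linda needs at least 5 taxa for reliable mode estimation (got %d)", ncol(clr))
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(clr)) stopf("meta rows must align with clr rows")
  tp <- factor(as.character(meta$timepoint),
               levels = unique(c(baseline, levels(factor(meta$timepoint)))))
  if (!baseline %in% tp) stopf("baseline timepoint '%s' absent from design", baseline)
  has_base <- tapply(tp == baseline, meta$subject_id, any)
  if (any(!has_base)) {
    bad <- names(has_base)[!has_base]
    warnf("excluding subject(s) without a %s sample: %s", baseline,
          paste(bad, collapse = ", "))
    keep <- !(meta$subject_id %in% bad)
    meta <- meta[keep, , drop = FALSE]
    clr <- clr[keep, , drop = FALSE]
    tp <- tp[keep]
  }
  d <- data.frame(
    y = clr[, 1L],
    treatment = factor(as.character(meta$treatment)),
    timepoint = droplevels(tp),
    subject = factor(meta$subject_id)
  )
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  fit0 <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ treatment * timepoint + (1 | subject), data = d, control = ctrl)))
  cn <- names(lme4::fixef(fit0))
  n_taxa <- ncol(clr)
  coef_raw <- se <- matrix(NA_real_, n_taxa, length(cn),
                           dimnames = list(colnames(clr), cn))
  re_sd <- numeric(n_taxa)
  for (j in seq_len(n_taxa)) {
    fj <- suppressWarnings(suppressMessages(lme4::refit(fit0, clr[, j])))
    coef_raw[j, ] <- lme4::fixef(fj)
    se[j, ] <- sqrt(diag(as.matrix(stats::vcov(fj))))
    vc <- as.data.frame(lme4::VarCorr(fj))
    re_sd[j] <- vc$sdcor[vc$grp == "subject"]
  }
  bias <- apply(coef_raw, 2L, kde_mode)
  bias_se <- apply(coef_raw, 2L, kde_mode_se)
  bias["(Intercept)"] <- 0  # intercept carries composition location, not effect bias
  bias_se["(Intercept)"] <- 0
  coef_corr <- sweep(coef_raw, 2L, bias)
  # the estimated bias is itself noisy when few taxa are available; its
  # bootstrap variance is propagated into the corrected-coefficient SE
  se_corr <- sqrt(sweep(se^2, 2L, bias_se^2, "+"))
  df_resid <- nrow(clr) - length(cn)
  tstat <- coef_corr / se_corr
  pval <- 2 * stats::pt(-abs(tstat), df = df_resid)
  out <- list(coef_raw = coef_raw, coef_corrected = coef_corr, se = se,
              se_corrected = se_corr,
              bias = bias, bias_se = bias_se, df = df_resid,
              re_sd = stats::setNames(re_sd, colnames(clr)),
              p = pval,
              treatment_levels = levels(d$treatment),
              timepoint_levels = levels(d$timepoint),
              baseline = baseline)
  class(out) <- "linda_fit"
  out
}

#' Day-0-anchored treated-vs-control fold changes per timepoint
#'
#' For each taxon and each non-baseline timepoint `t`, reports the contrast
#' `(treated_t - treated_d0) - (control_t - control_d0)` on the CLR scale,
#' i.e. the treatment x timepoint interaction coefficient of the
#' bias-corrected fit, divided by `ln 2` to give a log2 fold change. At the
#' baseline itself the contrast is identically zero and is not reported.
#' Benjamini-Hochberg FDR is applied across taxa within each timepoint (or
#' pooled over all taxa x timepoints).
#'
#' The default sign convention is `treated_minus_control` (positive = larger
#' day-0-anchored increase in the treated arm); `control_minus_treated`
#' flips the sign (the convention under which a negative value means an
#' increase in the treated arm).
#'
#' @param fits a `linda_fit`.
#' @param alpha confidence level for the normal-approximation CI
#'   (default 0.05 giving 95% CIs).
#' @param fdr_family `"per_timepoint"` (default) or `"pooled"`.
#' @param sign_convention see above.
#' @return data frame of class `fold_change_table`: `taxon`, `timepoint`,
#'   `log2fc`, `ci_low`, `ci_high`, `p`, `p_adj`.
#' @export
baseline_fold_changes <- function(fits, alpha = 0.05,
                                  fdr_family = c("per_timepoint", "pooled"),
                                  sign_convention = c("treated_minus_control",
                                                      "control_minus_treated")) {
  if (!inherits(fits, "linda_fit")) stopf("fits must be a linda_fit")
  fdr_family <- match.arg(fdr_family)
  sign_convention <- match.arg(sign_convention)
  trt <- fits$treatment_levels[2L]
  tps <- setdiff(fits$timepoint_levels, fits$baseline)
  cols <- paste0("treatment", trt, ":timepoint", tps)
  missing_cols <- setdiff(cols, colnames(fits$coef_corrected))
  if (length(missing_cols))
    stopf("interaction coefficient(s) not found: %s", paste(missing_cols, collapse = ", "))
  sgn <- if (sign_convention == "treated_minus_control") 1 else -1
  zq <- stats::qt(1 - alpha / 2, df = fits$df)
  recs <- do.call(rbind, lapply(seq_along(tps), function(i) {
    est <- sgn * fits$coef_corrected[, cols[i]] / log(2)
    sei <- fits$se_corrected[, cols[i]] / log(2)
    data.frame(taxon = rownames(fits$coef_corrected), timepoint = tps[i],
               log2fc = est, ci_low = est - zq * sei, ci_high = est + zq * sei,
               p = fits$p[, cols[i]], stringsAsFactors = FALSE, row.names = NULL)
  }))
  recs$p_adj <- if (fdr_family == "per_timepoint") {
    stats::ave(recs$p, recs$timepoint, FUN = function(p) stats::p.adjust(p, "BH"))
  } else stats::p.adjust(recs$p, "BH")
  attr(recs, "sign_convention") <- sign_convention
  attr(recs, "alpha") <- alpha
  class(recs) <- c("fold_change_table", "data.frame")
  recs
}
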