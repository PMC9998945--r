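cor_pvals <- function(r, n, method) {
  # analytic two-sided p-values: t approximation for Pearson/Spearman,
  # normal approximation for Kendall
  if (method %in% c("pearson", "spearman")) {
    r2 <- pmin(r^2, 1)
    t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(-t, df = n - 2)
    p[r2 >= 1] <- 0
  } else {
    z <- 3 * abs(r) * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * stats::pnorm(-z)
  }
  p
}

#' All pairwise correlations under three measures
#'
#' Computes Pearson's r, Spearman's rho and Kendall's tau with two-sided
#' p-values for every unordered feature pair of a CLR matrix (one stratum).
#' Constant features are excluded with a warning naming them.
#'
#' @param clr samples x features matrix.
#' @return data frame with one row per unordered pair: `feature_a`,
#'   `feature_b`, `r_pearson`, `p_pearson`, `rho`, `p_spearman`, `tau`,
#'   `p_kendall`; attribute `n` = number of samples.
#' @export
pairwise_correlations <- function(clr) {
  if (!is.matrix(clr)) clr <- as.matrix(clr)
  n <- nrow(clr)
  if (n < 5L) stopf("need at least 5 samples in the stratum (got %d)", n)
  sds <- apply(clr, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("excluding constant feature(s): %s",
          paste(colnames(clr)[sds == 0], collapse = ", "))
    clr <- clr[, sds > 0, drop = FALSE]
  }
  m <- ncol(clr)
  if (m < 2L) stopf("need at least 2 non-constant features")
  rp <- stats::cor(clr, method = "pearson")
  rs <- stats::cor(clr, method = "spearman")
  rk <- stats::cor(clr, method = "kendall")
  idx <- which(upper.tri(rp), arr.ind = TRUE)
  feats <- colnames(clr) %||% as.character(seq_len(m))
  out <- data.frame(
    feature_a = feats[idx[, 1L]],
    feature_b = feats[idx[, 2L]],
    r_pearson = rp[idx], p_pearson = cor_pvals(rp[idx], n, "pearson"),
    rho = rs[idx], p_spearman = cor_pvals(rs[idx], n, "spearman"),
    tau = rk[idx], p_kendall = cor_pvals(rk[idx], n, "kendall"),
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- n
  out
}

#' Consensus edge selection from a multi-measure correlation table
#'
#' Applies Benjamini-Hochberg FDR per measure across all pairs, then keeps an
#' edge iff at least `min_support` measures are individually significant
#' (adjusted p < `alpha`) and all supporting measures agree in sign; the
#' edge sign is that shared sign. Sign-conflicted edges are discarded.
#'
#' @param measures output of [pairwise_correlations()].
#' @param alpha significance level on adjusted p-values.
#' @param min_support minimum number of supporting measures (default 2).
#' @param fdr_family `"per_measure"` (default) or `"pooled"` (one BH family
#'   over all measures jointly).
#' @return data frame of class `edge_list`: feature pair, `sign` (`"+"` or
#'   `"-"`), `support` count, supporting-measure string, per-measure
#'   coefficients and adjusted p-values.
#' @export
consensus_edges <- function(measures, alpha = 0.05, min_support = 2L,
                            fdr_family = c("per_measure", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  meas <- c(pearson = "r_pearson", spearman = "rho", kendall = "tau")
  pcols <- c(pearson = "p_pearson", spearman = "p_spearman", kendall = "p_kendall")
  if (min_support > length(meas))
    stopf("min_support (%d) exceeds the number of measures (%d)",
          min_support, length(meas))
  if (fdr_family == "per_measure") {
    padj <- sapply(pcols, function(pc) stats::p.adjust(measures[[pc]], "BH"))
  } else {
    all_p <- unlist(measures[pcols], use.names = FALSE)
    adj <- stats::p.adjust(all_p, "BH")
    padj <- matrix(adj, ncol = length(pcols))
    colnames(padj) <- names(pcols)
  }
  padj <- matrix(padj, ncol = length(pcols), dimnames = list(NULL, names(pcols)))
  supp <- padj < alpha
  signs <- sapply(meas, function(mc) sign(measures[[mc]]))
  signs <- matrix(signs, ncol = length(meas), dimnames = list(NULL, names(meas)))
  n_supp <- rowSums(supp)
  agree <- vapply(seq_len(nrow(measures)), function(i) {
    s <- signs[i, supp[i, ]]
    length(s) == 0L || (all(s > 0) || all(s < 0))
  }, logical(1))
  keep <- n_supp >= min_support & agree
  edge_sign <- vapply(seq_len(nrow(measures)), function(i) {
    if (!keep[i]) return(NA_character_)
    if (signs[i, supp[i, ]][1L] > 0) "+" else "-"
  }, character(1))
  out <- data.frame(
    feature_a = measures$feature_a[keep],
    feature_b = measures$feature_b[keep],
    sign = edge_sign[keep],
    support = n_supp[keep],
    measures = vapply(which(keep), function(i)
      paste(names(meas)[supp[i, ]], collapse = ","), character(1)),
    r_pearson = measures$r_pearson[keep], p_adj_pearson = padj[keep, "pearson"],
    rho = measures$rho[keep], p_adj_spearman = padj[keep, "spearman"],
    tau = measures$tau[keep], p_adj_kendall = padj[keep, "kendall"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_support") <- min_support
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Summarize a consensus edge list
#'
#' Counts edges and the percent of positive edges, optionally per grouping
#' key (e.g. treatment arm x phase stratum). An empty group reports 0 edges
#' and `NA` percent positive.
#'
#' @param edges an `edge_list`, optionally with a `stratum` column.
#' @param by optional grouping column name (default `"stratum"` if present).
#' @return data frame: grouping key, `n_edges`, `n_positive`, `n_negative`,
#'   `percent_positive`.
#' @export
network_summary <- function(edges, by = NULL) {
  by <- by %||% (if ("stratum" %in% names(edges)) "stratum" else NULL)
  one <- function(e, key) {
    npos <- sum(e$sign == "+")
    nneg <- sum(e$sign == "-")
    data.frame(stratum = key, n_edges = npos + nneg, n_positive = npos,
               n_negative = nneg,
               percent_positive = if (npos + nneg > 0) 100 * npos / (npos + nneg) else NA_real_,
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(edges, "all"))
  keys <- unique(edges[[by]])
  do.call(rbind, lapply(keys, function(k) one(edges[edges[[by]] == k, , drop = FALSE], k)))
}

#' Consensus networks per stratum of a study
#'
#' Splits the samples by treatment arm x phase (default, matching how
#' pre/post interaction counts are summarized) or arm x timepoint, and runs
#' [pairwise_correlations()] + [consensus_edges()] within each stratum.
#'
#' @param clr samples x features CLR matrix.
#' @param meta per-sample design data frame.
#' @param group `"arm_phase"` (default) or `"arm_timepoint"`.
#' @param ... passed to [consensus_edges()].
#' @return an `edge_list` with a `stratum` column.
#' @export
networks_by_stratum <- function(clr, meta, group = c("arm_phase", "arm_timepoint"), ...) {
  group <- match.arg(group)
  key <- if (group == "arm_phase") paste(meta$treatment, meta$phase, sep = ".")
         else paste(meta$treatment, meta$timepoint, sep = ".")
  parts <- lapply(unique(key), function(k) {
    e <- consensus_edges(pairwise_correlations(clr[key == k, , drop = FALSE]), ...)
    if (nrow(e)) e$stratum <- k else e$stratum <- character(0)
    e
  })
  out <- do.call(rbind, parts)
  class(out) <- c("edge_list", "data.frame")
  out
}
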