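#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts by their posterior expectation under a Dirichlet
#' prior and rescales the observed parts multiplicatively, so ratios among
#' non-zero parts are preserved exactly. For a sample with total `n`, a zero
#' cell `j` becomes `r_j = t_j * s / (n + s)` (prior weight `t_j`, strength
#' `s`) and a non-zero cell with count `c_j` becomes
#' `(1 - sum_zeros r_k) * c_j / n`.
#'
#' @param counts samples x taxa non-negative matrix.
#' @param prior `"bayes_laplace"` (uniform `t_j = 1/D`, `s = D`; the
#'   deterministic default) or `"empirical"` (data-dependent weights
#'   proportional to overall taxon frequency).
#' @param prior_strength optional scalar `s` overriding the prior default.
#' @param prior_weights optional vector `t` (length = taxa, sums to 1)
#'   overriding the prior default.
#' @return composition matrix (rows sum to 1, all entries > 0).
#' @export
impute_zeros <- function(counts, prior = c("bayes_laplace", "empirical"),
                         prior_strength = NULL, prior_weights = NULL) {
  check_count_matrix(counts)
  prior <- match.arg(prior)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0] %||% which(totals == 0)
    stopf("sample(s) with all-zero counts: %s", paste(bad, collapse = ", "))
  }
  D <- ncol(counts)
  t_j <- prior_weights %||% switch(prior,
    bayes_laplace = rep(1 / D, D),
    empirical = (colSums(counts) + 0.5) / sum(colSums(counts) + 0.5)
  )
  if (length(t_j) != D || abs(sum(t_j) - 1) > 1e-8)
    stopf("prior_weights must have one entry per taxon and sum to 1")
  s <- prior_strength %||% D
  out <- counts / totals
  for (r in seq_len(nrow(counts))) {
    z <- counts[r, ] == 0
    if (!any(z)) next
    repl <- t_j[z] * s / (totals[r] + s)
    out[r, z] <- repl
    out[r, !z] <- (1 - sum(repl)) * counts[r, !z] / totals[r]
  }
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)_j = ln x_j - mean_k ln x_k` per sample (natural log). Rows of the
#' result sum to zero; the transform is invariant to per-sample rescaling.
#'
#' @param comp samples x features matrix of strictly positive values
#'   (proportions or imputed compositions).
#' @return real matrix of the same shape.
#' @export
clr_transform <- function(comp) {
  if (!is.matrix(comp)) comp <- as.matrix(comp)
  if (any(comp <= 0) || any(!is.finite(comp)))
    stopf("CLR requires strictly positive entries; impute zeros first (see impute_zeros)")
  lx <- log(comp)
  lx - rowMeans(lx)
}

#' Aitchison distances between samples
#'
#' Euclidean distance between CLR-transformed rows: the natural metric for
#' compositional data.
#'
#' @param clr samples x features CLR matrix.
#' @return object of class [stats::dist].
#' @export
aitchison_dist <- function(clr) {
  if (any(!is.finite(clr))) stopf("non-finite CLR values")
  stats::dist(clr)
}

#' Prevalence / mean-relative-abundance taxon filter with phase superset
#'
#' Within each stress phase a taxon passes if it is present (count > 0) in at
#' least `prevalence` of that phase's samples and its mean relative abundance
#' across the phase's samples exceeds `min_relabund`. The returned superset
#' is the union of the pre- and post-phase passing sets, the feature set used
#' for differential abundance.
#'
#' @param counts samples x taxa matrix.
#' @param phase per-sample labels, `"pre"` or `"post"`.
#' @param prevalence minimum presence fraction (default 0.75).
#' @param min_relabund minimum mean relative abundance on the proportion
#'   scale (default 1e-5, i.e. 0.001%).
#' @param scope `"per_phase"` (default) evaluates both criteria within each
#'   phase; `"all_samples"` evaluates them once over all samples.
#' @param abundance_rule `"mean"` (default) or `"max"`: whether the
#'   abundance criterion uses the mean or the per-sample maximum relative
#'   abundance within the phase.
#' @return list of class `taxon_set`: `pre_set`, `post_set`, `superset`,
#'   `thresholds`, and a per-taxon logical `report` data frame.
#' @export
prevalence_abundance_filter <- function(counts, phase, prevalence = 0.75,
                                        min_relabund = 1e-5,
                                        scope = c("per_phase", "all_samples"),
                                        abundance_rule = c("mean", "max")) {
  check_count_matrix(counts)
  scope <- match.arg(scope)
  abundance_rule <- match.arg(abundance_rule)
  phase <- as.character(phase)
  if (length(phase) != nrow(counts)) stopf("phase must have one label per sample")
  if (!all(phase %in% c("pre", "post")))
    stopf("unknown phase label(s): %s",
          paste(unique(setdiff(phase, c("pre", "post"))), collapse = ", "))
  if (scope == "per_phase" && length(unique(phase)) < 2L)
    stopf("phase labels must cover both pre and post")
  relab <- counts / rowSums(counts)
  pass_in <- function(rows) {
    prev <- colMeans(counts[rows, , drop = FALSE] > 0)
    ab <- if (abundance_rule == "mean") colMeans(relab[rows, , drop = FALSE])
          else apply(relab[rows, , drop = FALSE], 2L, max)
    prev >= prevalence & ab > min_relabund
  }
  taxa <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  if (scope == "per_phase") {
    pre_pass <- pass_in(phase == "pre")
    post_pass <- pass_in(phase == "post")
  } else {
    pre_pass <- post_pass <- pass_in(rep(TRUE, nrow(counts)))
  }
  res <- list(
    pre_set = taxa[pre_pass],
    post_set = taxa[post_pass],
    superset = taxa[pre_pass | post_pass],
    thresholds = list(prevalence = prevalence, min_relabund = min_relabund,
                      scope = scope, abundance_rule = abundance_rule),
    report = data.frame(taxon = taxa, pre_pass = unname(pre_pass),
                        post_pass = unname(post_pass),
                        in_superset = unname(pre_pass | post_pass))
  )
  class(res) <- "taxon_set"
  res
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples with fewer reads than `depth` are dropped with a warning.
#'
#' @param counts samples x taxa matrix.
#' @param depth target depth; default is the minimum sample total.
#' @param seed RNG seed for reproducible subsampling.
#' @return rarefied count matrix (every row sums to `depth`).
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  check_count_matrix(counts)
  totals <- rowSums(counts)
  depth <- depth %||% min(totals)
  if (depth <= 0) stopf("rarefaction depth must be positive")
  keep <- totals >= depth
  if (!all(keep))
    warnf("dropping %d sample(s) below rarefaction depth %d: %s",
          sum(!keep), depth, paste(rownames(counts)[!keep], collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- counts
  for (r in seq_len(nrow(counts))) {
    tot <- sum(counts[r, ])
    if (tot == depth) next
    pool <- rep.int(seq_len(ncol(counts)), counts[r, ])
    picked <- pool[sample.int(length(pool), depth)]
    out[r, ] <- tabulate(picked, nbins = ncol(counts))
  }
  storage.mode(out) <- "integer"
  out
}
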