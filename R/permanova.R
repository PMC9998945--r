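#' Gower double-centering of a distance matrix
#'
#' `G = -1/2 * J %*% D^2 %*% J` with `J = I - 11'/n`. The trace of `G` is
#' the total sum of squares of the configuration, the quantity PERMANOVA
#' partitions.
#'
#' @param d distance matrix or [stats::dist] object.
#' @return symmetric doubly centered matrix.
#' @export
gower_center <- function(d) {
  D <- as_dist_matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-10)) stopf("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm_), 2L, rm_) + gm
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix by the design
#' factors using sequential (Type-I) sums of squares via projections of the
#' Gower-centered matrix (McArdle-Anderson). Significance is assessed by
#' permuting sample labels: `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' With repeated-measures designs the default free permutation treats all
#' samples as exchangeable; pass `strata` (e.g. subject ids) to restrict
#' permutations within blocks. The returned object records which mode was
#' used.
#'
#' @param d distance matrix or `dist` among samples.
#' @param meta data frame of per-sample design factors, rows aligned with
#'   `d`.
#' @param terms ordered character vector of model terms (interactions via
#'   `:`), e.g. `c("treatment", "timepoint", "treatment:timepoint")`.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutation stream.
#' @param strata optional per-sample block labels; permutations shuffle
#'   samples only within a block.
#' @return data frame of class `permanova` with one row per term plus
#'   `Residual` and `Total`: `df`, `SS`, `R2`, `F`, `p`. Attributes:
#'   `n_perm`, `seed`, `permutation` (`"free"`/`"within_strata"`).
#' @export
permanova <- function(d, meta, terms, n_perm = 999L, seed = 1L, strata = NULL) {
  G <- gower_center(d)
  n <- nrow(G)
  if (nrow(meta) != n) stopf("meta rows must align with the distance matrix")
  if (n_perm < 99L) stopf("n_perm must be >= 99")
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) {
    if (!v %in% names(meta)) stopf("term variable '%s' not in meta", v)
    if (length(unique(meta[[v]])) < 2L)
      stopf("term '%s' has a single level", v)
  }
  md <- meta[, base_vars, drop = FALSE]
  md[] <- lapply(md, function(x) factor(as.character(x)))

  # sequential hat matrices: H_0 (intercept) .. H_k (all terms)
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  P <- vector("list", length(terms))  # per-term projection increments
  df <- integer(length(terms))
  for (i in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(i)]), md)
    H_i <- hat_matrix(X)
    P[[i]] <- H_i - H_prev
    df[i] <- qr(X)$rank - rank_prev
    rank_prev <- qr(X)$rank
    H_prev <- H_i
  }
  H_full <- H_prev
  R <- diag(n) - H_full
  df_res <- n - rank_prev

  f_stats <- function(Gm) {
    ss <- vapply(P, function(Pi) sum(Pi * Gm), numeric(1))
    ss_res <- sum(R * Gm)
    (ss / df) / (ss_res / df_res)
  }
  ss_obs <- vapply(P, function(Pi) sum(Pi * G), numeric(1))
  ss_res <- sum(R * G)
  total <- sum(diag(G))
  F_obs <- (ss_obs / df) / (ss_res / df_res)

  set.seed(seed)
  if (!is.null(strata) && length(strata) != n)
    stopf("strata must have one label per sample")
  perm_one <- if (is.null(strata)) {
    function() sample.int(n)
  } else {
    blocks <- split(seq_len(n), strata)
    function() {
      p <- integer(n)
      for (b in blocks) p[b] <- b[sample.int(length(b))]
      p
    }
  }
  geq <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- perm_one()
    Fp <- f_stats(G[p, p])
    geq <- geq + (Fp >= F_obs - 1e-12)
  }
  pval <- (1 + geq) / (1 + n_perm)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss_obs, ss_res, total),
    R2 = c(ss_obs, ss_res, total) / total,
    F = c(F_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "permutation") <- if (is.null(strata)) "free" else "within_strata"
  class(out) <- c("permanova", "data.frame")
  out
}
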