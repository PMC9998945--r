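#' Within-subject delta-CLR vs the day-0 baseline
#'
#' Subtracts, feature-wise, each subject's baseline (day-0) CLR row from the
#' subject's CLR row at every timepoint. Baseline rows become exactly zero;
#' subjects lacking a baseline sample are dropped with a warning.
#'
#' @param clr samples x features CLR matrix, rownames = sample ids.
#' @param meta per-sample design data frame aligned with `clr` rows.
#' @param baseline baseline timepoint label (default `"d0"`).
#' @return delta matrix with the same orientation as `clr` (rows restricted
#'   to retained subjects).
#' @export
delta_clr <- function(clr, meta, baseline = "d0") {
  if (!is.matrix(clr)) clr <- as.matrix(clr)
  if (nrow(meta) != nrow(clr)) stopf("meta rows must align with clr rows")
  tps <- unique(as.character(meta$timepoint))
  if (!baseline %in% tps) stopf("baseline timepoint '%s' absent from design", baseline)
  has_base <- tapply(as.character(meta$timepoint) == baseline, meta$subject_id, any)
  bad <- names(has_base)[!has_base]
  if (length(bad)) {
    warnf("dropping subject(s) without a %s sample: %s", baseline,
          paste(bad, collapse = ", "))
    keep <- !(meta$subject_id %in% bad)
    clr <- clr[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  base_rows <- which(as.character(meta$timepoint) == baseline)
  base_by_subj <- stats::setNames(base_rows, meta$subject_id[base_rows])
  clr - clr[base_by_subj[as.character(meta$subject_id)], , drop = FALSE]
}

item_dissimilarity <- function(x, kind) {
  # x: items x dims
  if (kind == "spearman") {
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
      stopf("constant item(s) under spearman dissimilarity: %s",
            paste((rownames(x) %||% as.character(seq_len(nrow(x))))[sds == 0],
                  collapse = ", "))
    stats::as.dist(1 - stats::cor(t(x), method = "spearman"))
  } else {
    stats::dist(x)
  }
}

#' Feature / sample dissimilarity for delta-CLR clustering
#'
#' `kind = "spearman"`: items are the features (columns) and
#' `d = 1 - rho` between feature profiles across rows — used for species and
#' CAZy identifiers. `kind = "aitchison_euclidean"`: items are the samples
#' (rows) and d is the Euclidean (Aitchison, since input is CLR-derived)
#' distance.
#'
#' @param delta delta-CLR matrix (rows samples, columns features).
#' @param kind `"spearman"` or `"aitchison_euclidean"`.
#' @return a [stats::dist] over the items.
#' @export
feature_dissimilarity <- function(delta, kind = c("spearman", "aitchison_euclidean")) {
  kind <- match.arg(kind)
  if (!is.matrix(delta)) delta <- as.matrix(delta)
  x <- if (kind == "spearman") t(delta) else delta
  if (nrow(x) < 3L) stopf("need at least 3 items")
  item_dissimilarity(x, kind)
}

pam_cost <- function(dm, medoids) sum(apply(dm[, medoids, drop = FALSE], 1L, min))

pam_once <- function(dm, k, medoids) {
  n <- nrow(dm)
  rows <- seq_len(n)
  repeat {
    dmed <- dm[, medoids, drop = FALSE]
    near_ix <- max.col(-dmed, ties.method = "first")
    dmin <- dmed[cbind(rows, near_ix)]
    if (k > 1L) {
      dmed[cbind(rows, near_ix)] <- Inf
      dsec <- dmed[cbind(rows, max.col(-dmed, ties.method = "first"))]
    } else dsec <- rep(Inf, n)
    cur_cost <- sum(dmin)
    cand <- rows[-medoids]
    best_gain <- 1e-12; best_swap <- NULL
    for (mi in seq_along(medoids)) {
      # distances to the remaining medoids if medoid mi is removed
      d_wo <- ifelse(near_ix == mi, dsec, dmin)
      costs <- colSums(pmin(dm[, cand, drop = FALSE], d_wo))
      ci <- which.min(costs)
      gain <- cur_cost - costs[ci]
      if (gain > best_gain) {
        best_gain <- gain
        best_swap <- c(mi, cand[ci])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
  }
  list(medoids = sort(medoids), cost = pam_cost(dm, medoids))
}

#' k-medoids (PAM) clustering on an arbitrary distance matrix
#'
#' Greedy build followed by exhaustive swap steps to a local optimum,
#' repeated from seeded random restarts; the best solution over restarts is
#' returned. Works for any dissimilarity (no Euclidean-mean assumption).
#'
#' @param d distance matrix or `dist` over items.
#' @param k number of clusters (1..n).
#' @param seed RNG seed for the restarts.
#' @param n_restarts random restarts in addition to the greedy build.
#' @return list of class `cluster_solution`: `clustering` (named integer
#'   vector), `medoids` (item ids), `k`, `cost` (total distance to medoids).
#' @export
cluster_kmedoids <- function(d, k, seed = 1L, n_restarts = 5L) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm) %||% as.character(seq_len(n))
  if (k < 1L || k > n) stopf("k must be in 1..%d (got %d)", n, k)
  if (k == n) {
    cl <- stats::setNames(seq_len(n), ids)
    return(structure(list(clustering = cl, medoids = ids, k = k, cost = 0),
                     class = "cluster_solution"))
  }
  set.seed(seed)
  # greedy build: start from the most central item, then add the item
  # giving the largest cost reduction
  medoids <- which.min(rowSums(dm))
  dmin <- dm[, medoids]
  while (length(medoids) < k) {
    cand <- seq_len(n)[-medoids]
    red <- colSums(pmax(dmin - dm[, cand, drop = FALSE], 0))
    medoids <- c(medoids, cand[which.max(red)])
    dmin <- pmin(dmin, dm[, medoids[length(medoids)]])
  }
  best <- pam_once(dm, k, medoids)
  for (r in seq_len(n_restarts)) {
    sol <- pam_once(dm, k, sample.int(n, k))
    if (sol$cost < best$cost - 1e-12) best <- sol
  }
  assign_ <- best$medoids[max.col(-dm[, best$medoids, drop = FALSE],
                                  ties.method = "first")]
  cl <- stats::setNames(match(assign_, best$medoids), ids)
  structure(list(clustering = cl, medoids = ids[best$medoids], k = k,
                 cost = best$cost),
            class = "cluster_solution")
}

within_dispersion <- function(dm2, clustering) {
  # W = sum over clusters of (1/(2 n_c)) * sum of squared within-cluster d
  sum(vapply(split(seq_along(clustering), clustering), function(ix)
    sum(dm2[ix, ix]) / (2 * length(ix)), numeric(1)))
}

#' Gap statistic for the number of clusters
#'
#' Compares the log within-cluster dispersion `log W_k` of k-medoids
#' partitions to its expectation under `B` reference datasets drawn
#' uniformly over each feature's observed range (Tibshirani's method "a").
#' `Gap(k) = mean_b log W*_kb - log W_k`,
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`, and the chosen k is the smallest
#' k with `Gap(k) >= Gap(k+1) - s_{k+1}` (else `k_max`).
#'
#' @param x items x dims coordinate matrix (for species/CAZy clustering pass
#'   the transposed delta-CLR matrix).
#' @param kind dissimilarity kind, as in [feature_dissimilarity()].
#' @param k_max largest k evaluated (< number of items).
#' @param B number of reference datasets (>= 10).
#' @param seed RNG seed.
#' @return list of class `gap_result`: `table` (k, logW, ElogW, gap, s_k),
#'   `chosen_k`, `B`, `seed`, and `solutions` (the `cluster_solution` per k).
#' @export
gap_statistic <- function(x, kind = c("spearman", "aitchison_euclidean"),
                          k_max = 7L, B = 50L, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (k_max >= n) stopf("k_max must be < number of items")
  if (B < 10L) stopf("B must be >= 10")
  if (all(stats::dist(x) < 1e-12)) {
    warnf("all items identical; returning k = 1")
    return(structure(list(table = NULL, chosen_k = 1L, B = B, seed = seed,
                          solutions = NULL), class = "gap_result"))
  }
  set.seed(seed)
  # observed
  dobs <- item_dissimilarity(x, kind)
  dm2_obs <- as_dist_matrix(dobs)^2
  sols <- vector("list", k_max)
  logW <- numeric(k_max)
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      sols[[k]] <- structure(list(clustering = stats::setNames(
        rep(1L, n), rownames(x) %||% as.character(seq_len(n))),
        medoids = NULL, k = 1L, cost = NA_real_), class = "cluster_solution")
    } else {
      sols[[k]] <- cluster_kmedoids(dobs, k, seed = sample.int(2^30, 1L),
                                    n_restarts = 2L)
    }
    logW[k] <- log(within_dispersion(dm2_obs, sols[[k]]$clustering))
  }
  # references: uniform over each column's observed range
  rng_lo <- apply(x, 2L, min); rng_hi <- apply(x, 2L, max)
  logWstar <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    xb <- matrix(stats::runif(n * ncol(x), rep(rng_lo, each = n),
                              rep(rng_hi, each = n)), n, ncol(x))
    db <- item_dissimilarity(xb, kind)
    dm2_b <- as_dist_matrix(db)^2
    for (k in seq_len(k_max)) {
      cl <- if (k == 1L) rep(1L, n)
            else cluster_kmedoids(db, k, seed = sample.int(2^30, 1L),
                                  n_restarts = 0L)$clustering
      logWstar[b, k] <- log(within_dispersion(dm2_b, cl))
    }
  }
  gap <- colMeans(logWstar) - logW
  s_k <- apply(logWstar, 2L, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - s_k[k + 1L]) { chosen <- k; break }
  }
  structure(list(
    table = data.frame(k = seq_len(k_max), logW = logW,
                       ElogW = colMeans(logWstar), gap = gap, s_k = s_k),
    chosen_k = chosen, B = B, seed = seed, solutions = sols),
    class = "gap_result")
}

#' Cluster occupancy by treatment arm and timepoint
#'
#' Fraction of each arm x timepoint cell's samples falling in each sample
#' cluster (the pie-chart summaries of clustering trajectories).
#'
#' @param solution a `cluster_solution` over samples (names = sample ids).
#' @param meta per-sample design data frame.
#' @return data frame: `treatment`, `timepoint`, `cluster`, `fraction`
#'   (fractions sum to 1 within each arm x timepoint).
#' @export
cluster_occupancy <- function(solution, meta) {
  cl <- solution$clustering
  ix <- match(meta$sample_id, names(cl))
  if (anyNA(ix)) stopf("clustering lacks sample(s): %s",
                       paste(meta$sample_id[is.na(ix)], collapse = ", "))
  tab <- table(treatment = meta$treatment, timepoint = meta$timepoint,
               cluster = cl[ix])
  out <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  tot <- stats::ave(out$n, out$treatment, out$timepoint, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$n / tot, NA_real_)
  out[out$n >= 0 & tot > 0, c("treatment", "timepoint", "cluster", "fraction")]
}
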