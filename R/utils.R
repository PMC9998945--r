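`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(m) {
  # subtract row max for numerical stability before exponentiation
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
}

check_count_matrix <- function(counts, min_dim = 2L) {
  if (!is.matrix(counts)) stopf("counts must be a matrix (samples x taxa)")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (nrow(counts) < min_dim || ncol(counts) < min_dim)
    stopf("count table needs at least %d samples and %d taxa", min_dim, min_dim)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stopf("duplicate sample or taxon identifiers in count table")
  invisible(counts)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two clusterings agree (both together or
#' both apart); 1 means identical partitions up to label permutation.
#'
#' @param a,b cluster label vectors over the same items.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must cover the same items")
  n <- length(a)
  if (n < 2L) return(1)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
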