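#' Write a count table as TSV (taxa rows, sample columns)
#'
#' @param counts samples x taxa matrix (internal orientation).
#' @param path output TSV path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(taxon = colnames(counts), t(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxa-rows-by-sample-columns TSV into a samples x taxa matrix
#'
#' @param path TSV path with a `taxon` (or first) id column.
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- as.character(raw[[1L]])
  m <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(m) <- taxa
  if (any(m < 0)) stopf("%s: negative counts", path)
  m
}

#' Read per-sample Bracken species reports into a count table
#'
#' Each file is one sample's Bracken species-abundance report (TSV with
#' columns `name`, `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`,
#' `added_reads`, `new_est_reads`, `fraction_total_reads`). Counts are taken
#' from `new_est_reads` and outer-joined across samples (zeros for species
#' absent from a sample). The reported `fraction_total_reads` is checked for
#' consistency against the count ratios (warning beyond a 1e-3 tolerance).
#'
#' @param paths character vector of report paths; names (or basenames) give
#'   the sample ids.
#' @return samples x species integer matrix.
#' @export
read_bracken <- function(paths) {
  required <- c("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
                "added_reads", "new_est_reads", "fraction_total_reads")
  ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  tabs <- lapply(seq_along(paths), function(i) {
    tb <- utils::read.delim(paths[i], check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(required, colnames(tb))
    if (length(miss))
      stopf("%s: missing required column(s): %s", paths[i], paste(miss, collapse = ", "))
    frac <- tb$new_est_reads / sum(tb$new_est_reads)
    if (any(abs(frac - tb$fraction_total_reads) > 1e-3))
      warnf("%s: fraction_total_reads inconsistent with new_est_reads ratios", paths[i])
    stats::setNames(tb$new_est_reads, tb$name)
  })
  taxa <- unique(unlist(lapply(tabs, names)))
  m <- matrix(0L, length(paths), length(taxa), dimnames = list(ids, taxa))
  for (i in seq_along(tabs)) m[i, names(tabs[[i]])] <- as.integer(tabs[[i]])
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
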