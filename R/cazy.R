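cazy_prefix_re <- "^(AA|CBM|CE|GH|GT|PL)[0-9]+$"

#' Load a taxon x CAZy-family profile table
#'
#' Reads a TSV whose first column is the taxon id and whose remaining
#' columns are CAZy family counts. Family names must carry one of the six
#' CAZy class prefixes (AA, CBM, CE, GH, GT, PL) followed by the family
#' number; entries must be non-negative integers; taxon ids must be unique.
#'
#' @param path TSV file path.
#' @return validated integer matrix taxa x families.
#' @export
load_cazy_profiles <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stopf("%s: need a taxon column plus at least one family", path)
  taxa <- as.character(raw[[1L]])
  if (anyDuplicated(taxa))
    stopf("%s: duplicate taxon id(s): %s", path,
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  fam <- colnames(raw)[-1L]
  bad_fam <- fam[!grepl(cazy_prefix_re, fam)]
  if (length(bad_fam))
    stopf("%s: family name(s) with unknown class prefix: %s", path,
          paste(bad_fam, collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    ij <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1L, ]
    stopf("%s: invalid entry at taxon '%s', family '%s'", path,
          taxa[ij[1L]], fam[ij[2L]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- taxa
  m
}

#' Accumulate CAZy potential per sample
#'
#' Combines per-taxon CAZy family profiles with a sample x taxon count table
#' into a sample x family table. `presence` mode (default) sums the family
#' counts of every taxon detected (count > 0) in the sample, irrespective of
#' its abundance; `abundance` mode weights each taxon's profile by its
#' relative abundance. Taxa present in the counts but missing from the
#' profiles are treated as all-zero with a warning.
#'
#' @param profiles taxa x families matrix (see [load_cazy_profiles()]).
#' @param counts samples x taxa count matrix.
#' @param mode `"presence"` or `"abundance"`.
#' @return samples x families matrix (integer in presence mode); attribute
#'   `mode` records the accumulation mode.
#' @export
accumulate_cazy <- function(profiles, counts, mode = c("presence", "abundance")) {
  mode <- match.arg(mode)
  if (!is.matrix(profiles) || !is.matrix(counts))
    stopf("profiles and counts must be matrices")
  missing_taxa <- setdiff(colnames(counts), rownames(profiles))
  if (length(missing_taxa)) {
    warnf("taxa without CAZy profile treated as all-zero: %s",
          paste(missing_taxa, collapse = ", "))
    zero <- matrix(0L, length(missing_taxa), ncol(profiles),
                   dimnames = list(missing_taxa, colnames(profiles)))
    profiles <- rbind(profiles, zero)
  }
  prof <- profiles[colnames(counts), , drop = FALSE]
  out <- if (mode == "presence") {
    m <- (counts > 0) %*% prof
    storage.mode(m) <- "integer"
    m
  } else {
    (counts / rowSums(counts)) %*% prof
  }
  attr(out, "mode") <- mode
  out
}
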