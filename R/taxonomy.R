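RANKS <- c("phylum", "class", "order", "family", "genus")

#' Read a taxonomy map
#'
#' Delimited text with a `taxon_id` column and rank columns
#' `phylum, class, order, family, genus`; empty strings or NA mean
#' "unassigned at this rank".
#'
#' @inheritParams read_count_table
#' @return data.frame with `taxon_id` row names and one column per rank.
#' @export
read_taxonomy <- function(path, delim = "\t") {
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"taxon_id" %in% names(df))
    stop_ug("taxonomy '%s' lacks a taxon_id column", path)
  missing <- setdiff(RANKS, names(df))
  if (length(missing) > 0)
    stop_ug("taxonomy '%s' lacks rank column(s): %s", path,
            paste(missing, collapse = ", "))
  rownames(df) <- df$taxon_id
  df
}

#' Agglomerate a count table to a taxonomic rank
#'
#' Taxa (e.g. ASVs) sharing the same label at `rank` are summed. Taxa
#' unassigned at `rank` are grouped under
#' `"unclassified_<lowest assigned rank>_<label>"` so that reads are never
#' silently discarded; taxa unassigned at every rank group under
#' `"unclassified"`. Per-sample totals are conserved exactly.
#'
#' @param x count table (samples x taxa).
#' @param taxonomy data.frame as returned by [read_taxonomy()]; every taxon
#'   of `x` must appear in its row names.
#' @param rank one of `"phylum", "class", "order", "family", "genus"`.
#' @return agglomerated count table; columns carry the rank labels.
#' @export
agglomerate <- function(x, taxonomy, rank = "genus") {
  x <- validate_count_table(x)
  rank <- match.arg(rank, RANKS)
  absent <- setdiff(colnames(x), rownames(taxonomy))
  if (length(absent) > 0)
    stop_ug("taxa missing from taxonomy: %s", paste(absent, collapse = ", "))
  keys <- vapply(colnames(x), function(tid) {
    agglom_key(taxonomy[tid, , drop = FALSE], rank)
  }, character(1))
  groups <- split(seq_len(ncol(x)), keys)
  out <- vapply(groups, function(idx) rowSums(x[, idx, drop = FALSE]),
                numeric(nrow(x)))
  if (nrow(x) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(x), names(groups)))
  storage.mode(out) <- "integer"
  validate_count_table(out)
  out
}

# Grouping key for one taxon at the requested rank.
agglom_key <- function(row, rank) {
  label <- row[[rank]]
  if (!is.na(label) && nzchar(label)) return(label)
  upto <- RANKS[seq_len(match(rank, RANKS))]
  assigned <- upto[!is.na(unlist(row[upto])) & nzchar(unlist(row[upto]))]
  if (length(assigned) == 0) return("unclassified")
  lowest <- assigned[length(assigned)]
  sprintf("unclassified_%s_%s", lowest, row[[lowest]])
}
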