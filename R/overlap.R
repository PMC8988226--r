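#' Genus presence set
#'
#' Genera with nonzero count in at least one of the selected samples of a
#' (post-filter) count table.
#'
#' @param x count table.
#' @param samples sample ids to consider (default: all).
#' @return character vector of genera.
#' @export
presence_set <- function(x, samples = NULL) {
  x <- validate_count_table(x)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(x))
    if (length(missing) > 0)
      stop_ug("unknown sample(s): %s", paste(missing, collapse = ", "))
    if (length(samples) == 0) stop_ug("empty sample subset")
    x <- x[samples, , drop = FALSE]
  }
  colnames(x)[colSums(x) > 0]
}

#' Overlap between two genus sets
#'
#' Shared fraction is Jaccard-style, `|A intersect B| / |A union B|`;
#' because the convention behind published percentages can differ, the
#' per-site fractions `|A intersect B| / |A|` and `|A intersect B| / |B|`
#' are also returned. Both sets empty gives `NA` fractions.
#'
#' @param set_a,set_b character vectors of genera.
#' @return list: `shared`, `unique_a`, `unique_b`, `shared_fraction`
#'   (Jaccard), `fraction_of_a`, `fraction_of_b`.
#' @export
genus_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- sort(intersect(set_a, set_b))
  un <- union(set_a, set_b)
  list(shared = shared,
       unique_a = sort(setdiff(set_a, set_b)),
       unique_b = sort(setdiff(set_b, set_a)),
       shared_fraction = if (length(un) == 0) NA_real_ else length(shared) / length(un),
       fraction_of_a = if (length(set_a) == 0) NA_real_ else length(shared) / length(set_a),
       fraction_of_b = if (length(set_b) == 0) NA_real_ else length(shared) / length(set_b))
}

#' Median relative abundance of shared genera by site
#'
#' For each shared genus and each site, the median percent relative
#' abundance over the samples in which the genus is present (nonzero);
#' optionally over all samples. Rows are grouped by phylum and sorted by
#' descending site-A median within phylum (the convention of
#' "ranked by median abundance in the vaginal community" summaries).
#'
#' @param x_a,x_b count tables for the two sites (e.g. vaginal, bladder).
#' @param shared genera to report (subset of both tables' taxa).
#' @param phylum named character vector mapping genus to phylum; genera
#'   missing from it cause an error.
#' @param presence_only median over presence-only samples (default TRUE).
#' @return data.frame `genus, phylum, median_a, median_b` in report order.
#' @export
median_abundance_table <- function(x_a, x_b, shared, phylum,
                                   presence_only = TRUE) {
  for (tab in list(x_a, x_b)) {
    absent <- setdiff(shared, colnames(tab))
    if (length(absent) > 0)
      stop_ug("shared genera absent from table: %s", paste(absent, collapse = ", "))
  }
  unmapped <- setdiff(shared, names(phylum))
  if (length(unmapped) > 0)
    stop_ug("genera absent from taxonomy: %s", paste(unmapped, collapse = ", "))
  med <- function(tab, g) {
    rel <- relative_abundance(tab)[, g] * 100
    if (presence_only) rel <- rel[rel > 0]
    if (length(rel) == 0) NA_real_ else median(rel)
  }
  out <- data.frame(genus = shared,
                    phylum = unname(phylum[shared]),
                    median_a = vapply(shared, function(g) med(x_a, g), numeric(1)),
                    median_b = vapply(shared, function(g) med(x_b, g), numeric(1)),
                    row.names = NULL)
  # group phyla by their top site-A median, then sort within phylum
  phy_rank <- tapply(out$median_a, out$phylum, max)
  out <- out[order(-phy_rank[out$phylum], out$phylum, -out$median_a, out$genus), ]
  rownames(out) <- NULL
  out
}
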