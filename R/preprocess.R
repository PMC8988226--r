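#' Rarefy a count table without replacement
#'
#' Each sample is subsampled uniformly without replacement to exactly
#' `depth` reads (a multivariate hypergeometric draw). Samples with fewer
#' than `depth` reads are dropped, reported via a message, and recorded in
#' the `"dropped_samples"` attribute of the result (named vector of their
#' totals). Dropping is not an error.
#'
#' @param x count table (samples x taxa).
#' @param depth target reads per sample (>= 1).
#' @param seed optional integer seed; identical seeds give identical output.
#' @return rarefied count table with every row total equal to `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  x <- validate_count_table(x)
  if (length(depth) != 1 || is.na(depth) || depth < 1)
    stop_ug("rarefaction depth must be a positive integer, got %s", format(depth))
  depth <- as.integer(depth)
  tot <- rowSums(x)
  drop <- tot < depth
  dropped <- tot[drop]
  if (any(drop))
    message(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(sprintf("%s (%d)", names(dropped), dropped), collapse = ", ")))
  keep <- x[!drop, , drop = FALSE]
  out <- with_seed_if(seed, {
    t(apply(keep, 1, rarefy_one, depth = depth))
  })
  dimnames(out) <- dimnames(keep)
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- dropped
  out
}

# Hypergeometric subsample of one sample's reads.
rarefy_one <- function(counts, depth) {
  total <- sum(counts)
  if (total == depth) return(counts)
  picked <- sample.int(total, depth)
  cum <- cumsum(counts)
  tabulate(findInterval(picked, cum, left.open = TRUE) + 1L,
           nbins = length(counts))
}

#' Filter taxa by maximum per-sample relative abundance
#'
#' Keeps exactly the taxa whose relative abundance strictly exceeds
#' `threshold` in at least one sample ("greater than", not "at least");
#' the sample set is unchanged. Idempotent.
#'
#' @param x count table.
#' @param threshold fraction in (0, 1); default 0.05 (5%).
#' @return filtered count table.
#' @export
abundance_filter <- function(x, threshold = 0.05) {
  if (length(threshold) != 1 || threshold < 0 || threshold >= 1)
    stop_ug("threshold must lie in [0, 1), got %s", format(threshold))
  rel <- relative_abundance(x)
  keep <- apply(rel, 2, max) > threshold
  x[, keep, drop = FALSE]
}

#' Frequency-based contaminant screening
#'
#' Scores each taxon by comparing, on the samples where it is present, the
#' fit of a contaminant model (log relative abundance linear in log DNA
#' concentration with slope fixed at -1) against a constant-frequency null
#' model. Both models are fit by least squares in log-log space; the score
#' is `pf(RSS_contam / RSS_null, n - 1, n - 1)`, an F-type tail probability
#' in `[0, 1]` where smaller means more contaminant-like. Taxa with score
#' below `score_threshold` are removed. Taxa present in fewer than
#' `min_prevalence` samples are not scored (the two one-parameter models are
#' not distinguishable) and are retained. Scores are invariant to rescaling
#' all concentrations by a positive constant.
#'
#' @param x count table.
#' @param dna_concentration positive numeric vector named by sample id (or
#'   in row order of `x`).
#' @param score_threshold removal threshold on the score; 0.3 was used for
#'   bladder samples and 0.5 for vaginal samples in the motivating study.
#' @param min_prevalence minimum number of samples with nonzero count needed
#'   to score a taxon (default 5).
#' @return list with `table` (filtered counts), `scores` (data.frame of
#'   taxon, prevalence, score, contaminant flag) and `removed` (character).
#' @export
decontam_frequency <- function(x, dna_concentration, score_threshold = 0.3,
                               min_prevalence = 5) {
  x <- validate_count_table(x)
  conc <- dna_concentration
  if (!is.null(names(conc))) {
    missing <- setdiff(rownames(x), names(conc))
    if (length(missing) > 0)
      stop_ug("missing DNA concentration for sample(s): %s",
              paste(missing, collapse = ", "))
    conc <- conc[rownames(x)]
  } else if (length(conc) != nrow(x)) {
    stop_ug("dna_concentration must have one value per sample")
  }
  if (anyNA(conc) || any(conc <= 0))
    stop_ug("all DNA concentrations must be positive")
  rel <- relative_abundance(x)
  logc <- log(conc)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    present <- rel[, j] > 0
    if (sum(present) < min_prevalence) return(NA_real_)
    y <- log(rel[present, j])
    xc <- logc[present]
    n <- length(y)
    rss_contam <- sum((y + xc - mean(y + xc))^2)   # slope -1, free intercept
    rss_null <- sum((y - mean(y))^2)                # constant frequency
    if (rss_null == 0 && rss_contam == 0) return(0.5)
    if (rss_null == 0) return(1)
    pf(rss_contam / rss_null, n - 1, n - 1)
  }, numeric(1))
  flagged <- !is.na(scores) & scores < score_threshold
  res <- data.frame(taxon = colnames(x),
                    prevalence = colSums(x > 0),
                    score = scores,
                    contaminant = flagged,
                    row.names = NULL)
  list(table = x[, !flagged, drop = FALSE],
       scores = res,
       removed = colnames(x)[flagged])
}
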