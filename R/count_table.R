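#' Validate a count table
#'
#' A count table is a plain integer matrix with samples in rows and taxa in
#' columns, uniquely named on both dimensions. All pipeline functions accept
#' and return this representation.
#'
#' @param x matrix to validate.
#' @param what label used in error messages.
#' @return `x`, invisibly, with counts coerced to integer storage.
#' @export
validate_count_table <- function(x, what = "count table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_ug("%s must be a numeric matrix (samples x taxa)", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_ug("%s must have sample row names and taxon column names", what)
  if (anyDuplicated(rownames(x)))
    stop_ug("%s has duplicate sample ids: %s", what,
            paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_ug("%s has duplicate taxon ids: %s", what,
            paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop_ug("%s contains missing values", what)
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_ug("%s has negative count at sample '%s', taxon '%s'", what,
            rownames(x)[neg[1, 1]], colnames(x)[neg[1, 2]])
  if (any(abs(x - round(x)) > 1e-8)) {
    bad <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)
    stop_ug("%s has non-integer count at sample '%s', taxon '%s'", what,
            rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]])
  }
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Read and write count tables
#'
#' Tables are stored as delimited text with one header row of taxon ids and
#' the first column holding sample ids (rows = samples). `read_count_table()`
#' validates on read and fails on ragged rows, duplicate identifiers,
#' negative or non-integer cells, naming the offending entry.
#'
#' @param path file path.
#' @param delim field delimiter, `"\t"` (default) or `","`.
#' @param taxa_as `"columns"` (default) if taxa are table columns, or
#'   `"rows"` if the file is transposed (taxa x samples).
#' @return an integer samples x taxa matrix.
#' @export
read_count_table <- function(path, delim = "\t", taxa_as = c("columns", "rows")) {
  taxa_as <- match.arg(taxa_as)
  if (!file.exists(path)) stop_ug("count table file not found: %s", path)
  if (file.size(path) == 0) stop_ug("count table file is empty: %s", path)
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                   row.names = 1, comment.char = "", quote = "\"",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0)
    stop_ug("count table '%s' has no data rows or columns", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- colnames(df)[!vapply(df, is.numeric, logical(1))][1]
    stop_ug("non-numeric entries in column '%s' of %s", bad, path)
  }
  if (taxa_as == "rows") m <- t(m)
  validate_count_table(m, sprintf("count table '%s'", path))
}

#' @rdname read_count_table
#' @param x validated count table (samples x taxa).
#' @export
write_count_table <- function(x, path, delim = "\t") {
  x <- validate_count_table(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param x count table (samples x taxa).
#' @return numeric matrix whose rows sum to one.
#' @export
relative_abundance <- function(x) {
  x <- validate_count_table(x)
  tot <- rowSums(x)
  if (any(tot == 0))
    stop_ug("zero-total sample(s): %s",
            paste(rownames(x)[tot == 0], collapse = ", "))
  sweep(x, 1, tot, "/")
}

#' Read sample metadata
#'
#' Expects a delimited file with a `sample_id` column plus arbitrary
#' covariates (`cohort`, `site`, `age`, `bmi`, `menopause`, `estrogen_use`,
#' `vaginal_product_use`, `dna_concentration`, ...).
#'
#' @inheritParams read_count_table
#' @return data.frame with `sample_id` row names.
#' @export
read_sample_metadata <- function(path, delim = "\t") {
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop_ug("metadata '%s' lacks a sample_id column", path)
  if (anyDuplicated(df$sample_id))
    stop_ug("metadata '%s' has duplicate sample ids", path)
  rownames(df) <- df$sample_id
  df
}

#' @rdname read_sample_metadata
#' @param metadata data.frame with a `sample_id` column.
#' @export
write_sample_metadata <- function(metadata, path, delim = "\t") {
  write.table(metadata, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
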