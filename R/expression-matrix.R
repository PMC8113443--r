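#' Expression matrix with a declared unit
#'
#' A light S3 container for a feature-by-sample matrix of nonnegative
#' abundances. The unit is declared explicitly (`count`, `RPM`, `RPKM` or
#' `TPM`) so that downstream operations can refuse unit mismatches instead of
#' silently mixing scales. Optional per-feature metadata (biotype, chromosome,
#' strand, length in bp) travels with the matrix.
#'
#' @param values numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs). All values must be >= 0.
#' @param unit one of `"count"`, `"RPM"`, `"RPKM"`, `"TPM"`.
#' @param feature_meta optional data.frame with one row per feature; recognised
#'   columns are `biotype`, `chrom`, `strand` and `length`.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, unit, feature_meta = NULL) {
  values <- as.matrix(values)
  unit <- match.arg(unit, c("count", "RPM", "RPKM", "TPM"))
  fid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) > 0L)
    pt_assert(!is.null(fid), "missing_ids", "feature IDs (rownames) are required")
  if (ncol(values) > 0L)
    pt_assert(!is.null(sid), "missing_ids", "sample IDs (colnames) are required")
  pt_assert(!anyDuplicated(fid), "duplicate_id", "duplicate feature IDs: %s",
            paste(unique(fid[duplicated(fid)]), collapse = ", "))
  pt_assert(!anyDuplicated(sid), "duplicate_id", "duplicate sample IDs: %s",
            paste(unique(sid[duplicated(sid)]), collapse = ", "))
  pt_assert(is.numeric(values), "malformed_numeric", "values must be numeric")
  pt_assert(!anyNA(values), "malformed_numeric", "values contain NA")
  pt_assert(all(values >= 0), "negative_value", "expression values must be >= 0")
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    pt_assert(nrow(feature_meta) == nrow(values), "meta_mismatch",
              "feature_meta must have one row per feature")
    if ("strand" %in% names(feature_meta))
      pt_assert(all(feature_meta$strand %in% c("+", "-", ".")), "bad_strand",
                "strand must be one of +, -, .")
    if ("length" %in% names(feature_meta)) {
      len <- feature_meta$length
      pt_assert(all(is.na(len) | len > 0), "bad_length", "feature lengths must be > 0")
    }
    rownames(feature_meta) <- fid
  }
  structure(list(values = values, unit = unit, feature_meta = feature_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$feature_meta))
    cat("  feature_meta:", paste(names(x$feature_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

META_COLS <- c("biotype", "chrom", "strand", "length")

#' Read an expression matrix from TSV
#'
#' The first column holds feature IDs; columns named `biotype`, `chrom`,
#' `strand` or `length` are treated as feature metadata; all remaining columns
#' are samples. [write_expression_matrix()] followed by this function
#' round-trips exactly for finite decimal inputs.
#'
#' @param path TSV file path.
#' @param unit declared unit of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  pt_assert(ncol(df) >= 1, "malformed_file", "no columns in %s", path)
  fid <- df[[1L]]
  meta_cols <- intersect(META_COLS, names(df)[-1L])
  sample_cols <- setdiff(names(df)[-1L], meta_cols)
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(fid, sample_cols))
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- is.na(v) & !is.na(df[[s]])
    pt_assert(!any(bad), "malformed_numeric",
              "non-numeric value '%s' in column '%s'",
              df[[s]][which(bad)[1L]], s)
    vals[, s] <- v
  }
  meta <- NULL
  if (length(meta_cols)) {
    meta <- df[meta_cols]
    if ("length" %in% meta_cols)
      meta$length <- suppressWarnings(as.numeric(meta$length))
  }
  expression_matrix(vals, unit = unit, feature_meta = meta)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @param id_col name for the feature-ID column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_col = "feature_id") {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(rownames(x$values), stringsAsFactors = FALSE)
  names(out) <- id_col
  if (!is.null(x$feature_meta))
    out <- cbind(out, x$feature_meta)
  # as.character() prints up to 15 significant digits, enough for decimals
  # parsed from text to survive a write/read cycle unchanged
  for (s in colnames(x$values)) out[[s]] <- as.character(x$values[, s])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
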