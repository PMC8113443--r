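#' Genomic interval sets
#'
#' Intervals are stored 0-based half-open (BED convention) in a plain
#' data.frame with columns `chrom`, `start`, `end`, `id`, `score`, `strand`.
#' Text coordinates of the form `"chr1:100-200"` (1-based inclusive, commas
#' permitted) are converted at the boundary by [text_coords_to_interval()].
#'
#' @param chrom,start,end,id,score,strand interval fields; `start < end`
#'   (0-based half-open), `strand` in `+`, `-`, `.`.
#' @param multiplicity optional positive integer per interval: the number of
#'   identical sequenced copies a collapsed small-RNA read represents.
#' @return a data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, id = NULL, score = 0L,
                         strand = ".", multiplicity = NULL) {
  n <- length(start)
  if (is.null(id)) id <- if (n) paste0("iv", seq_len(n)) else character(0)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start), end = as.integer(end),
                   id = as.character(id),
                   score = rep_len(score, n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  pt_assert(all(df$start < df$end), "bad_interval",
            "start must be < end (0-based half-open); offending id(s): %s",
            paste(utils::head(df$id[df$start >= df$end], 3), collapse = ", "))
  pt_assert(all(df$strand %in% c("+", "-", ".")), "bad_strand",
            "strand must be one of +, -, .")
  if (!is.null(multiplicity)) {
    df$multiplicity <- as.integer(rep_len(multiplicity, n))
    pt_assert(all(df$multiplicity >= 1L), "bad_multiplicity",
              "multiplicity must be >= 1")
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

# Mitochondrial naming is normalized at ingestion ("MT" -> "chrM").
normalize_chrom <- function(chrom) {
  chrom <- ifelse(chrom %in% c("MT", "chrMT"), "chrM", chrom)
  chrom
}

#' Read a BED6 file as an interval set
#'
#' Uses rtracklayer's BED importer; order is preserved and the 0-based
#' half-open convention is kept. Zero-length or inverted intervals raise a
#' classed error.
#'
#' @param path BED file path.
#' @param require_strand error if any record lacks a strand (`*`/`.`).
#' @return an [interval_set()].
#' @export
read_interval_set <- function(path, require_strand = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  if (require_strand)
    pt_assert(all(strand %in% c("+", "-")), "missing_strand",
              "strand required but absent for some records in %s", path)
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- paste0("iv", seq_along(gr))
  sc <- gr$score
  if (is.null(sc)) sc <- 0L
  sc[is.na(sc)] <- 0L
  start0 <- GenomicRanges::start(gr) - 1L  # back to BED 0-based
  end0 <- GenomicRanges::end(gr)
  pt_assert(all(start0 < end0), "bad_interval",
            "zero-length or inverted interval in %s", path)
  interval_set(normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
               start0, end0, id = nm, score = sc, strand = strand)
}

#' Write an interval set as BED6
#' @param x an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interval_set <- function(x, path) {
  out <- data.frame(x$chrom, x$start, x$end, x$id, x$score,
                    ifelse(x$strand == ".", ".", x$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval_set -> GRanges (1-based closed internally for IRanges machinery)
as_granges <- function(x) {
  strand <- ifelse(x$strand == ".", "*", x$strand)
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end),
                               strand = strand)
  S4Vectors::mcols(gr)$id <- x$id
  if (!is.null(x$multiplicity)) S4Vectors::mcols(gr)$multiplicity <- x$multiplicity
  gr
}

#' Convert paper-style text coordinates to a half-open interval
#'
#' `"chr19:53,686,484-53,752,432"` (1-based inclusive) becomes the 0-based
#' half-open interval `[53686483, 53752432)`; its length is `E - S + 1`.
#'
#' @param text a string `"chrom:S-E"`; commas in numbers are ignored.
#' @return a one-row [interval_set()] with an extra `length` column.
#' @export
text_coords_to_interval <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1L]]
  pt_assert(length(m) == 4L, "bad_coords", "cannot parse coordinates '%s'", text)
  s <- suppressWarnings(as.numeric(gsub(",", "", m[3L])))
  e <- suppressWarnings(as.numeric(gsub(",", "", m[4L])))
  pt_assert(!is.na(s) && !is.na(e), "bad_coords", "non-numeric coordinates in '%s'", text)
  pt_assert(s <= e, "bad_coords", "start > end in '%s'", text)
  iv <- interval_set(m[2L], s - 1, e, id = text)
  iv$length <- iv$end - iv$start
  iv
}

#' Format a half-open interval back to 1-based inclusive text
#' @param iv a one-row [interval_set()].
#' @param big_mark thousands separator (default `","`, matching printed style).
#' @return a string `"chrom:S-E"`.
#' @export
interval_to_text_coords <- function(iv, big_mark = ",") {
  sprintf("%s:%s-%s", iv$chrom,
          formatC(iv$start + 1, format = "d", big.mark = big_mark),
          formatC(iv$end, format = "d", big.mark = big_mark))
}

#' Minimum sample count for a presence threshold
#'
#' Converts a cohort fraction into the minimum number of samples a feature
#' must be seen in. With `strict = FALSE` ("present in at least 30%"), the
#' answer is `ceiling(fraction * n)`; with `strict = TRUE` ("present in more
#' than 10%") it is `floor(fraction * n) + 1`. For a 295-sample cohort these
#' give 89 (30%) and 30 (>10%).
#'
#' @param n_samples cohort size (>= 1).
#' @param fraction presence fraction in (0, 1].
#' @param strict `FALSE` for at-least semantics, `TRUE` for strictly-greater.
#' @return an integer count.
#' @export
presence_min_count <- function(n_samples, fraction, strict = FALSE) {
  pt_assert(n_samples >= 1, "bad_n", "n_samples must be >= 1")
  pt_assert(fraction > 0 && fraction <= 1, "bad_fraction",
            "fraction must be in (0, 1]")
  m <- fraction * n_samples
  eps <- 1e-9 * max(1, abs(m))  # guard float noise around integers
  if (strict) as.integer(floor(m + eps)) + 1L else as.integer(ceiling(m - eps))
}
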