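# Transcriptome-complexity statistics: unit conversions, TA50, cumulative
# abundance curves, top-fraction shares and abundance-class tables.

# round-half-away-from-zero, so that 0.05 * 5000 = 250 and 0.03 * 5000 = 150
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

#' Convert counts to reads per million (RPM)
#'
#' @param x an [expression_matrix()] of unit `"count"`.
#' @return an [expression_matrix()] of unit `"RPM"`; every column sums to 1e6.
#' @export
counts_to_rpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  pt_assert(x$unit == "count", "unit_mismatch", "input unit must be count, got %s", x$unit)
  tot <- colSums(x$values)
  pt_assert(all(tot > 0), "zero_total", "column total is zero for sample(s): %s",
            paste(colnames(x$values)[tot == 0], collapse = ", "))
  expression_matrix(sweep(x$values, 2, tot, "/") * 1e6, "RPM", x$feature_meta)
}

#' Convert counts to RPKM
#'
#' `RPKM_i = count_i * 1e9 / (column_total * length_i)`. Lengths come from
#' `feature_meta$length` unless supplied.
#'
#' @param x an [expression_matrix()] of unit `"count"`.
#' @param lengths optional per-feature lengths in bp.
#' @return an [expression_matrix()] of unit `"RPKM"`.
#' @export
counts_to_rpkm <- function(x, lengths = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  pt_assert(x$unit == "count", "unit_mismatch", "input unit must be count, got %s", x$unit)
  if (is.null(lengths)) lengths <- x$feature_meta$length
  pt_assert(!is.null(lengths) && !anyNA(lengths), "missing_length",
            "feature lengths are required for RPKM")
  pt_assert(all(lengths > 0), "bad_length", "feature lengths must be > 0")
  tot <- colSums(x$values)
  pt_assert(all(tot > 0), "zero_total", "column total is zero")
  vals <- sweep(x$values, 2, tot, "/") * 1e9 / lengths
  expression_matrix(vals, "RPKM", x$feature_meta)
}

#' Rescale RPKM to TPM
#'
#' `TPM_i = RPKM_i / sum_j RPKM_j * 1e6`; the output sums to 1e6 per profile.
#' Idempotent up to scale: applying it twice equals applying it once.
#'
#' @param rpkm numeric vector or matrix (features x samples) of RPKM values.
#' @return same shape, TPM scale.
#' @export
rpkm_to_tpm <- function(rpkm) {
  if (is.matrix(rpkm)) {
    tot <- colSums(rpkm)
    pt_assert(all(tot > 0), "zero_total", "all-zero RPKM column")
    return(sweep(rpkm, 2, tot, "/") * 1e6)
  }
  tot <- sum(rpkm)
  pt_assert(tot > 0, "zero_total", "all-zero RPKM input")
  rpkm / tot * 1e6
}

#' TA50: transcripts needed to reach half of total abundance
#'
#' Transcripts are sorted in descending abundance (ties broken by name for
#' determinism) and the smallest k whose cumulative abundance reaches 50% of
#' the total is reported, along with the fraction k/n. A highly skewed
#' transcriptome has a small TA50; a uniform one of n transcripts has
#' `ceiling(n/2)`.
#'
#' @param abundances named or unnamed nonnegative vector; total must be > 0.
#' @return list with `count`, `fraction`, `total_abundance`, `top_ids`.
#' @export
ta50 <- function(abundances) {
  pt_assert(length(abundances) > 0, "empty_input", "empty abundance profile")
  pt_assert(all(abundances >= 0), "negative_value", "abundances must be >= 0")
  tot <- sum(abundances)
  pt_assert(tot > 0, "zero_total", "total abundance is zero")
  nm <- names(abundances)
  if (is.null(nm)) nm <- sprintf("f%06d", seq_along(abundances))
  o <- order(-abundances, nm)
  cum <- cumsum(abundances[o])
  k <- unname(which(cum >= 0.5 * tot)[1L])
  list(count = k, fraction = k / length(abundances), total_abundance = tot,
       top_ids = nm[o][seq_len(k)])
}

#' Share of total abundance held by the top fraction of transcripts
#'
#' @param abundances nonnegative vector, total > 0.
#' @param fraction fraction of transcripts in (0, 1]; the top
#'   `max(1, round(fraction * n))` transcripts are taken.
#' @return share of total abundance in (0, 1].
#' @export
top_fraction_share <- function(abundances, fraction) {
  pt_assert(length(abundances) > 0, "empty_input", "empty abundance profile")
  pt_assert(fraction > 0 && fraction <= 1, "bad_fraction", "fraction must be in (0,1]")
  tot <- sum(abundances)
  pt_assert(tot > 0, "zero_total", "total abundance is zero")
  k <- max(1L, round_half_up(fraction * length(abundances)))
  sum(sort(abundances, decreasing = TRUE)[seq_len(k)]) / tot
}

ABUNDANCE_CLASSES <- c("undetected", "(0,0.1)", "[0.1,1)", "[1,100]",
                       "(100,1000]", "(1000,1e4]", ">1e4")

classify_abundance <- function(v) {
  cls <- character(length(v))
  cls[v == 0] <- "undetected"
  cls[v > 0     & v < 0.1]  <- "(0,0.1)"
  cls[v >= 0.1  & v < 1]    <- "[0.1,1)"
  cls[v >= 1    & v <= 100] <- "[1,100]"
  cls[v > 100   & v <= 1e3] <- "(100,1000]"
  cls[v > 1e3   & v <= 1e4] <- "(1000,1e4]"
  cls[v > 1e4]              <- ">1e4"
  factor(cls, levels = ABUNDANCE_CLASSES)
}

#' Abundance-class table by biotype
#'
#' Bins each feature's abundance into the classes undetected (= 0), (0, 0.1),
#' \[0.1, 1), \[1, 100\], (100, 1000\], (1000, 1e4\] and > 1e4 on the declared
#' unit, and reports per-biotype proportions (each row sums to 1). No plotting
#' pseudo-count is applied: "not detected" means exactly zero.
#'
#' @param abundances nonnegative vector (one profile, e.g. per-sample or a
#'   row-mean summary), or a single-column [expression_matrix()].
#' @param biotypes character vector of biotype labels, one per feature.
#' @param allow_unlabeled if `FALSE` (default) features with `NA` biotype are
#'   rejected; if `TRUE` they are pooled under `"other"`.
#' @return matrix of proportions, biotypes x classes.
#' @export
abundance_class_table <- function(abundances, biotypes, allow_unlabeled = FALSE) {
  if (inherits(abundances, "expr_matrix")) {
    pt_assert(abundances$unit %in% c("RPKM", "RPM"), "unit_mismatch",
              "abundance classes are defined on RPKM or RPM")
    pt_assert(ncol(abundances$values) == 1L, "bad_shape",
              "supply a single profile (one column); summarize multi-sample matrices first")
    abundances <- abundances$values[, 1L]
  }
  pt_assert(length(abundances) == length(biotypes), "meta_mismatch",
            "one biotype label per feature required")
  if (anyNA(biotypes)) {
    pt_assert(allow_unlabeled, "unlabeled_feature",
              "features without biotype present; set allow_unlabeled = TRUE to pool them")
    biotypes[is.na(biotypes)] <- "other"
  }
  tab <- table(biotype = biotypes, class = classify_abundance(abundances))
  prop <- prop.table(tab, margin = 1)
  unclass(prop)
}

#' Cumulative abundance curve
#'
#' Transcripts sorted in descending abundance; returns (rank fraction,
#' cumulative share) pairs. The curve is nondecreasing, concave, and ends at
#' share 1.
#'
#' @param abundances nonnegative vector, total > 0.
#' @return data.frame with columns `rank_fraction`, `cumulative_share`.
#' @export
cumulative_abundance_curve <- function(abundances) {
  pt_assert(length(abundances) > 0, "empty_input", "empty abundance profile")
  tot <- sum(abundances)
  pt_assert(tot > 0, "zero_total", "total abundance is zero")
  s <- sort(abundances, decreasing = TRUE)
  n <- length(s)
  data.frame(rank_fraction = seq_len(n) / n,
             cumulative_share = cumsum(s) / tot)
}
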