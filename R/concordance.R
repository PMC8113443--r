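# Bootstrap fold-change concordance between two phenotypes: eligibility
# filtering, paired bootstrap fold changes, abundance-restricted top-k
# selection, the direction-aware Fisher sharing test, BH adjustment and
# correlation screens.

#' Eligibility rules for differential-expression candidates
#'
#' Defaults follow the filter set used for case-control placental cohorts:
#' RPM >= 0.2 (count >= 5 for circRNAs), present in strictly more than 10% of
#' each cohort's samples, found in both cohorts, and not on chrY or chrMT.
#'
#' @param rpm_min,circ_count_min abundance thresholds.
#' @param presence_frac cohort presence fraction in (0, 1), strict (>).
#' @param excluded_chroms chromosomes removed outright.
#' @return a named list of rules.
#' @export
eligibility_rules <- function(rpm_min = 0.2, circ_count_min = 5,
                              presence_frac = 0.10,
                              excluded_chroms = c("chrY", "chrMT")) {
  pt_assert(rpm_min > 0 && circ_count_min > 0, "bad_threshold",
            "thresholds must be positive")
  pt_assert(presence_frac > 0 && presence_frac < 1, "bad_fraction",
            "presence_frac must be in (0, 1)")
  list(rpm_min = rpm_min, circ_count_min = circ_count_min,
       presence_frac = presence_frac, excluded_chroms = excluded_chroms)
}

#' Filter transcripts eligible for differential-expression analysis
#'
#' A transcript is eligible iff, in EACH cohort, the number of samples with
#' value at or above the threshold strictly exceeds `presence_frac` of that
#' cohort's size, and its chromosome is not excluded. The threshold is
#' `rpm_min` for RPM matrices and `circ_count_min` for count matrices
#' (circRNA convention).
#'
#' @param x an [expression_matrix()] of unit `"RPM"` (or `"count"` for
#'   circRNAs).
#' @param cohorts named list of sample-ID vectors, one per cohort.
#' @param rules from [eligibility_rules()].
#' @return character vector of eligible feature IDs.
#' @export
de_eligibility_filter <- function(x, cohorts, rules = eligibility_rules()) {
  stopifnot(inherits(x, "expr_matrix"))
  pt_assert(x$unit %in% c("RPM", "count"), "unit_mismatch",
            "eligibility is defined on RPM (or counts for circRNA), got %s", x$unit)
  thr <- if (x$unit == "RPM") rules$rpm_min else rules$circ_count_min
  ids <- rownames(x$values)
  ok <- rep(TRUE, length(ids))
  if (!is.null(x$feature_meta$chrom)) {
    chrom <- normalize_chrom(x$feature_meta$chrom)
    excl <- normalize_chrom(rules$excluded_chroms)
    ok <- ok & !(chrom %in% excl)
  }
  for (samples in cohorts) {
    pt_assert(all(samples %in% colnames(x$values)), "unmapped_sample",
              "cohort sample(s) missing from the matrix")
    need <- presence_min_count(length(samples), rules$presence_frac, strict = TRUE)
    ok <- ok & rowSums(x$values[, samples, drop = FALSE] >= thr) >= need
  }
  ids[ok]
}

#' Bootstrap fold changes over matched case-control pairs
#'
#' For each of `n_boot` replicates, the sampling unit (matched pairs by
#' default) is resampled with replacement to its original count; the
#' replicate fold change of transcript i is the ratio of resampled case and
#' control means, `FC_i^k = mean(case RPM) / mean(control RPM)`; the reported
#' `FC_i` is the arithmetic mean of `FC_i^k` over replicates, with `log2(FC_i)`
#' alongside. Replicates where transcript i's control mean is zero are
#' dropped from that transcript's mean and counted in `n_dropped`.
#'
#' @param case_mat,control_mat matrices, transcripts x pairs, column j of each
#'   holding the case and matched control of pair j.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param unit `"pairs"` (resample matched pairs jointly; default) or
#'   `"independent"` (resample cases and controls separately).
#' @return list of class `bootstrap_fc`: `fc`, `log2_fc`, `n_dropped`,
#'   `mc_se` (Monte-Carlo SE of each `fc`), `n_boot`, `seed`, `unit`.
#' @export
bootstrap_fold_changes <- function(case_mat, control_mat, n_boot = 10000,
                                   seed = 1L, unit = c("pairs", "independent")) {
  unit <- match.arg(unit)
  case_mat <- as.matrix(case_mat); control_mat <- as.matrix(control_mat)
  pt_assert(n_boot >= 1, "bad_n", "n_boot must be >= 1")
  pt_assert(ncol(case_mat) == ncol(control_mat), "bad_shape",
            "cases and controls must be paired (equal columns)")
  n <- ncol(case_mat)
  pt_assert(n >= 2, "bad_shape", "need >= 2 pairs")
  pt_assert(all(case_mat >= 0) && all(control_mat >= 0), "negative_value",
            "expression values must be >= 0")
  p <- nrow(case_mat)
  fc_sum <- numeric(p); fc_sumsq <- numeric(p); n_ok <- integer(p)
  set.seed(seed)
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cidx <- if (unit == "pairs") idx else sample.int(n, n, replace = TRUE)
    cm <- rowSums(case_mat[, idx, drop = FALSE]) / n
    km <- rowSums(control_mat[, cidx, drop = FALSE]) / n
    ok <- km > 0
    fck <- cm[ok] / km[ok]
    fc_sum[ok] <- fc_sum[ok] + fck
    fc_sumsq[ok] <- fc_sumsq[ok] + fck * fck
    n_ok[ok] <- n_ok[ok] + 1L
  }
  fc <- ifelse(n_ok > 0, fc_sum / n_ok, NA_real_)
  vhat <- ifelse(n_ok > 1, pmax(0, (fc_sumsq - n_ok * fc^2) / (n_ok - 1)), NA_real_)
  ids <- rownames(case_mat)
  res <- list(fc = stats::setNames(fc, ids),
              log2_fc = stats::setNames(log2(fc), ids),
              n_dropped = stats::setNames(n_boot - n_ok, ids),
              mc_se = stats::setNames(sqrt(vhat / pmax(n_ok, 1)), ids),
              n_boot = n_boot, seed = seed, unit = unit)
  class(res) <- "bootstrap_fc"
  res
}

#' @export
print.bootstrap_fc <- function(x, ...) {
  cat(sprintf("<bootstrap_fc> %d transcripts, %d replicates (unit = %s, seed = %d)\n",
              length(x$fc), x$n_boot, x$unit, x$seed))
  invisible(x)
}

#' Select top-ranked transcripts within the abundance subset
#'
#' The `round(abundance_subset_ratio * n)` most abundant transcripts form the
#' eligible subset (the magnitude of a fold change is unreliable for poorly
#' expressed transcripts); within it, transcripts are ranked by |log2 FC|
#' descending (ties by ID) and the top `round(top_frac * k_abund)` are
#' selected, each carrying the sign of its log2 FC. Rounding is
#' half-away-from-zero so a 5000-transcript subset yields exactly 250 at 5%
#' and 150 at 3%.
#'
#' @param boot a `bootstrap_fc` (or a named log2-FC vector).
#' @param abundance named abundance vector (e.g. mean RPM) over the same
#'   transcripts.
#' @param abundance_subset_ratio fraction of transcripts kept by abundance
#'   (default 5000/15257).
#' @param top_frac fraction of the abundance subset to select, in (0, 1].
#' @return list of class `top_set`: `ids`, `signs` (+1/-1 named by ID),
#'   `k_abund`, `abundance_ids` (the whole abundance subset), `top_frac`.
#' @export
select_top_ranked <- function(boot, abundance,
                              abundance_subset_ratio = 5000 / 15257,
                              top_frac = 0.05) {
  pt_assert(top_frac > 0 && top_frac <= 1, "bad_fraction", "top_frac in (0, 1]")
  log2_fc <- if (inherits(boot, "bootstrap_fc")) boot$log2_fc else boot
  ids <- names(log2_fc)
  pt_assert(!is.null(ids) && all(ids %in% names(abundance)), "missing_ids",
            "abundance must cover every transcript")
  n <- length(ids)
  k_abund <- max(1L, as.integer(round_half_up(abundance_subset_ratio * n)))
  ab <- abundance[ids]
  sub_ids <- ids[order(-ab, ids)][seq_len(k_abund)]
  lfc <- log2_fc[sub_ids]
  keep <- !is.na(lfc)
  ranked <- sub_ids[keep][order(-abs(lfc[keep]), sub_ids[keep])]
  m <- max(1L, as.integer(round_half_up(top_frac * k_abund)))
  pt_assert(m <= length(ranked), "bad_fraction",
            "top_frac selects more transcripts than have defined fold changes")
  sel <- ranked[seq_len(m)]
  structure(list(ids = sel,
                 signs = stats::setNames(ifelse(log2_fc[sel] >= 0, 1L, -1L), sel),
                 k_abund = k_abund, abundance_ids = sub_ids,
                 top_frac = top_frac),
            class = "top_set")
}

#' Direction-aware Fisher sharing test between two top sets
#'
#' Counts transcripts shared by both top sets with the same fold-change
#' direction (`n_same`) and builds the 2x2 table
#' `(n_same, k - n_same; k - n_same, N - 2k + n_same)` over the background of
#' the N transcripts in the union of the two abundance subsets, then applies
#' the two-sided Fisher exact test. With k = 250 selected from each condition
#' over N = 5214 background transcripts and 92 shared in the same direction,
#' the table is (92, 158; 158, 4806).
#'
#' @param set_a,set_b `top_set` objects from [select_top_ranked()].
#' @param background_n background size N; default: size of the union of the
#'   two abundance subsets.
#' @return list of class `overlap_test`: `n_same`, `n_opposite`, `k`, `n`,
#'   `table` (2x2 matrix), `p`.
#' @export
overlap_concordance_test <- function(set_a, set_b, background_n = NULL) {
  k_a <- length(set_a$ids); k_b <- length(set_b$ids)
  pt_assert(k_a == k_b, "bad_shape",
            "top sets must be of equal size (k = %d vs %d)", k_a, k_b)
  k <- k_a
  if (is.null(background_n))
    background_n <- length(union(set_a$abundance_ids, set_b$abundance_ids))
  pt_assert(background_n >= 2 * k - k, "bad_shape",
            "background smaller than a top set")
  shared <- intersect(set_a$ids, set_b$ids)
  n_same <- sum(set_a$signs[shared] == set_b$signs[shared])
  n_opposite <- length(shared) - n_same
  tab <- matrix(c(n_same, k - n_same, k - n_same,
                  background_n - 2L * k + n_same), 2L, 2L, byrow = TRUE)
  pt_assert(all(tab >= 0), "bad_shape", "background too small for the margins")
  structure(list(n_same = n_same, n_opposite = n_opposite, k = k,
                 n = background_n, table = tab, p = fisher_exact_2x2(tab)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> %d/%d shared same-direction (+%d opposite), N = %d, P = %.3g\n",
              x$n_same, x$k, x$n_opposite, x$n, x$p))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric point
#' probabilities not exceeding that of the observed table (relative tolerance
#' 1e-7 on the comparison). Point masses are evaluated in log space, so
#' P values down to ~1e-300 are representable. A table with a zero margin has
#' a single attainable configuration and P = 1.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer counts.
#' @return the two-sided P value.
#' @export
fisher_exact_2x2 <- function(tab) {
  a <- as.vector(t(as.matrix(tab)))
  pt_assert(length(a) == 4L, "bad_shape", "need a 2x2 table")
  pt_assert(all(a >= 0), "negative_cell", "cells must be >= 0")
  pt_assert(all(abs(a - round(a)) < 1e-8), "bad_cell", "cells must be integers")
  a <- as.numeric(round(a))
  r1 <- a[1] + a[2]; r2 <- a[3] + a[4]
  c1 <- a[1] + a[3]; c2 <- a[2] + a[4]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- stats::dhyper(support, c1, c2, r1, log = TRUE)
  log_obs <- stats::dhyper(a[1], c1, c2, r1, log = TRUE)
  sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p P values in \[0, 1\].
#' @return adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  pt_assert(all(p >= 0 & p <= 1, na.rm = TRUE), "bad_p", "P values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-matrix correlation screen
#'
#' Computes all pairwise correlations between the rows of two feature x sample
#' matrices over their shared samples (Spearman by default), retains features
#' attaining `|rho| >= rho_threshold` with at least one partner, and reports
#' BH-adjusted P values (asymptotic t approximation) for the retained pairs.
#' Constant features yield `NA` correlations and are reported as missing, not
#' as errors.
#'
#' @param mat_a,mat_b matrices, features x samples, sharing column names.
#' @param method correlation method (default `"spearman"`).
#' @param rho_threshold absolute-correlation retention threshold.
#' @return list with `pairs` (data.frame feature_a, feature_b, rho, p, p_adj
#'   for pairs at/above threshold), `retained_a`, `retained_b`, `rho` (full
#'   matrix).
#' @export
correlation_screen <- function(mat_a, mat_b, method = "spearman",
                               rho_threshold = 0.4) {
  shared <- intersect(colnames(mat_a), colnames(mat_b))
  pt_assert(length(shared) >= 3, "bad_shape", "need >= 3 shared samples")
  A <- t(mat_a[, shared, drop = FALSE]); B <- t(mat_b[, shared, drop = FALSE])
  rho <- suppressWarnings(stats::cor(A, B, method = method))
  n <- length(shared)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tstat), df = n - 2)
  hit <- !is.na(rho) & abs(rho) >= rho_threshold
  idx <- which(hit, arr.ind = TRUE)
  p_all <- pmat[!is.na(pmat)]
  p_adj_mat <- pmat
  p_adj_mat[!is.na(pmat)] <- bh_adjust(p_all)  # adjust over every tested pair
  pairs <- data.frame(feature_a = rownames(rho)[idx[, 1L]],
                      feature_b = colnames(rho)[idx[, 2L]],
                      rho = rho[idx], p = pmat[idx], p_adj = p_adj_mat[idx],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p, pairs$feature_a, pairs$feature_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       retained_a = rownames(rho)[rowSums(hit) > 0],
       retained_b = colnames(rho)[colSums(hit) > 0],
       rho = rho)
}
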