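# Tissue-enrichment scoring: TMM normalization, per-tissue TPM summarization,
# the Tau tissue-specificity index and strict/relaxed enrichment flagging.

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization (Robinson &
#' Oshlack): the reference column is the one whose 75th-percentile count
#' fraction is closest to the mean across columns; per-gene log2 count-fraction
#' ratios (M) and average log2 fractions (A) are doubly trimmed (30% on M, 5%
#' on A by default) and the factor is 2 to the precision-weighted mean of the
#' retained M values, with inverse asymptotic binomial variances as weights.
#' Factors are rescaled to multiply to 1. Delegates to
#' `edgeR::calcNormFactors(method = "TMM")`, the implementation used with
#' placental/GTEx count matrices in practice.
#'
#' @param counts nonnegative count matrix, genes x samples (>= 2 samples).
#' @param logratio_trim two-sided trim fraction on M (default 0.30).
#' @param abs_trim two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of per-sample factors; `prod(factors) == 1`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  pt_assert(ncol(counts) >= 2, "bad_shape", "TMM needs at least 2 samples")
  tot <- colSums(counts)
  pt_assert(all(tot > 0), "zero_total", "column total is zero")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratio.trim = logratio_trim,
                              sum.trim = abs_trim)
  pt_assert(all(is.finite(f) & f > 0), "degenerate_column",
            "a column shares no positive genes with the reference")
  names(f) <- colnames(counts)
  f
}

#' Per-tissue mean TPM panel
#'
#' Collapses a count matrix with many samples per tissue to one TPM column per
#' tissue: counts are scaled by TMM-adjusted library sizes (and gene length,
#' when available) to per-sample expression, averaged within tissue, and each
#' tissue column is rescaled to TPM (sums to 1e6).
#'
#' @param x an [expression_matrix()] of unit `"count"`.
#' @param tissue_of named character vector mapping every sample ID to a tissue.
#' @param factors TMM factors from [tmm_factors()] (default: computed).
#' @param lengths optional gene lengths in bp (uses `feature_meta$length` when
#'   present; without lengths the per-sample measure is CPM, which is
#'   proportional to TPM when lengths are equal).
#' @return a `tissue_panel`: list with `tpm` (gene x tissue), `tissues`.
#' @export
mean_tpm_by_tissue <- function(x, tissue_of, factors = NULL, lengths = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  sid <- colnames(x$values)
  pt_assert(all(sid %in% names(tissue_of)), "unmapped_sample",
            "unmapped sample(s): %s",
            paste(setdiff(sid, names(tissue_of)), collapse = ", "))
  if (is.null(factors)) factors <- tmm_factors(x$values)
  pt_assert(all(factors > 0), "bad_factor", "TMM factors must be positive")
  if (is.null(lengths)) lengths <- x$feature_meta$length
  eff_lib <- colSums(x$values) * factors[sid]
  per_sample <- sweep(x$values, 2, eff_lib, "/") * 1e6   # CPM on effective libs
  if (!is.null(lengths) && !anyNA(lengths))
    per_sample <- per_sample * 1e3 / lengths             # -> RPKM-like
  tiss <- tissue_of[sid]
  agg <- vapply(split(seq_along(sid), tiss),
                function(ix) rowMeans(per_sample[, ix, drop = FALSE]),
                numeric(nrow(per_sample)))
  tpm <- rpkm_to_tpm(agg)
  structure(list(tpm = tpm, tissues = colnames(tpm)), class = "tissue_panel")
}

#' Tau tissue-specificity score
#'
#' With expression normalized to the maximum tissue,
#' `Tau = sum_i (1 - x_i / max) / (n - 1)`. Tau is 0 for a uniform profile,
#' 1 for expression confined to a single tissue, and scale-invariant.
#'
#' @param x nonnegative expression vector across n >= 2 tissues, max > 0.
#' @return Tau in \[0, 1\].
#' @export
tau <- function(x) {
  pt_assert(length(x) >= 2, "bad_shape", "Tau needs >= 2 tissues")
  pt_assert(all(x >= 0), "negative_value", "expression must be >= 0")
  mx <- max(x)
  pt_assert(mx > 0, "zero_total", "Tau undefined for an all-zero profile")
  sum(1 - x / mx) / (length(x) - 1)
}

#' Enrichment thresholds (strict and relaxed presets)
#'
#' Strict: Tau > 0.99, query TPM > 1, query TPM > 100 x mean of remaining
#' tissues. Relaxed (used for endogenous-retrovirus candidates): Tau > 0.9
#' and a 10x fold rule.
#'
#' @param tau_min,tpm_min,fold_over_rest numeric thresholds.
#' @return a named list of thresholds.
#' @export
enrichment_thresholds <- function(tau_min = 0.99, tpm_min = 1,
                                  fold_over_rest = 100) {
  pt_assert(tau_min > 0 && tau_min <= 1, "bad_threshold", "tau_min in (0,1]")
  pt_assert(fold_over_rest > 1, "bad_threshold", "fold_over_rest must be > 1")
  list(tau_min = tau_min, tpm_min = tpm_min, fold_over_rest = fold_over_rest)
}

#' @rdname enrichment_thresholds
#' @export
relaxed_thresholds <- function() enrichment_thresholds(0.9, 1, 10)

#' Flag tissue-enriched genes
#'
#' A gene is enriched in tissue t iff Tau > `tau_min`, TPM_t > `tpm_min`,
#' TPM_t > `fold_over_rest` x the arithmetic mean TPM of the other tissues,
#' and its biotype is eligible. Under the strict defaults a gene can be
#' enriched in at most one tissue.
#'
#' @param panel a `tissue_panel` from [mean_tpm_by_tissue()], or a plain
#'   gene x tissue TPM matrix.
#' @param thresholds from [enrichment_thresholds()].
#' @param biotypes optional per-gene biotype labels.
#' @param eligible_biotypes biotypes allowed to be flagged (default
#'   protein-coding and lincRNA); ignored when `biotypes` is `NULL`.
#' @param exclude optional gene IDs to drop first (e.g. non-polyadenylated
#'   histone genes when comparing against poly-A selected references).
#' @return data.frame of flagged (gene, tissue) rows with `tau`, `tpm`,
#'   `fold_over_rest` columns.
#' @export
flag_tissue_enriched <- function(panel, thresholds = enrichment_thresholds(),
                                 biotypes = NULL,
                                 eligible_biotypes = c("protein_coding", "lincRNA"),
                                 exclude = NULL) {
  tpm <- if (inherits(panel, "tissue_panel")) panel$tpm else as.matrix(panel)
  pt_assert(ncol(tpm) >= 2, "bad_shape", "need >= 2 tissues")
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tpm)))
  keep <- rep(TRUE, nrow(tpm))
  if (!is.null(exclude)) keep <- keep & !(genes %in% exclude)
  if (!is.null(biotypes)) {
    pt_assert(length(biotypes) == nrow(tpm), "meta_mismatch",
              "one biotype per gene required")
    keep <- keep & biotypes %in% eligible_biotypes
  }
  n_t <- ncol(tpm)
  out <- vector("list", n_t)
  rs <- rowSums(tpm)
  taus <- rep(NA_real_, nrow(tpm))
  pos <- which(apply(tpm, 1, max) > 0)
  taus[pos] <- apply(tpm[pos, , drop = FALSE], 1, tau)
  for (j in seq_len(n_t)) {
    rest_mean <- (rs - tpm[, j]) / (n_t - 1)
    hit <- keep & !is.na(taus) & taus > thresholds$tau_min &
      tpm[, j] > thresholds$tpm_min &
      tpm[, j] > thresholds$fold_over_rest * rest_mean
    if (any(hit))
      out[[j]] <- data.frame(gene = genes[hit], tissue = colnames(tpm)[j],
                             tau = taus[hit], tpm = tpm[hit, j],
                             fold_over_rest = tpm[hit, j] / pmax(rest_mean[hit], .Machine$double.xmin),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene = character(0), tissue = character(0),
                      tau = numeric(0), tpm = numeric(0),
                      fold_over_rest = numeric(0))
  rownames(res) <- NULL
  res
}

#' Observed/expected over-representation ratio with a chi-squared test
#'
#' Reports `observed / expected` and a goodness-of-fit chi-squared against the
#' expectation. When `total` is given, the Pearson statistic is computed over
#' the cell and its complement; otherwise the one-cell statistic
#' `(obs - exp)^2 / exp` is used. P comes from the chi-squared distribution
#' with 1 df. The expectation model is the caller's: `expected` is an explicit
#' input.
#'
#' @param observed,expected nonnegative counts, `expected > 0`.
#' @param total optional grand total for a two-cell Pearson statistic.
#' @return list with `ratio`, `chisq`, `p`.
#' @export
enrichment_over_representation <- function(observed, expected, total = NULL) {
  pt_assert(expected > 0, "bad_expected", "expected must be > 0")
  if (is.null(total)) {
    stat <- (observed - expected)^2 / expected
  } else {
    pt_assert(total >= max(observed, expected), "bad_total",
              "total must be >= observed and expected")
    stat <- (observed - expected)^2 / expected +
      ((total - observed) - (total - expected))^2 / (total - expected)
  }
  list(ratio = observed / expected, chisq = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
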