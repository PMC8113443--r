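# Serum-biomarker analysis: multiples of the median, the log-linear
# covariate correction, percentile dichotomization, odds ratios and exact
# tests (the case-cohort FSTL3 design).

#' Multiples of the median (MoM)
#'
#' `MoM_i = conc_i / median(reference)`; the reference subset's own MoMs have
#' median exactly 1.
#'
#' @param concentrations positive analyte concentrations.
#' @param reference positive concentrations of the reference sub-cohort.
#' @return MoM values.
#' @export
compute_mom <- function(concentrations, reference) {
  pt_assert(length(reference) > 0, "empty_input", "reference is empty")
  pt_assert(all(concentrations > 0) && all(reference > 0), "nonpositive_value",
            "concentrations must be > 0")
  concentrations / stats::median(reference)
}

#' Fit the log-linear MoM correction on a reference sub-cohort
#'
#' Ordinary least squares of `log10(MoM)` on gestational age (weeks), maternal
#' weight (kg) and sample storage time (years), fitted on the random
#' sub-cohort only. The fitted coefficients feed [apply_mom_correction()].
#'
#' @param table data.frame with columns `concentration`, `GA`, `WT`, `SST`
#'   (the reference sub-cohort rows).
#' @param mom optional precomputed MoM values (default: computed against the
#'   table's own concentrations).
#' @return list of class `mom_fit`: `coefficients` (intercept, b_GA, c_WT,
#'   d_SST on the log10 scale), `se`, `sigma`, `r_squared`, `fit` (the lm).
#' @export
fit_mom_correction <- function(table, mom = NULL) {
  pt_assert(nrow(table) >= 10, "bad_shape", "need >= 10 reference subjects")
  pt_assert(all(c("GA", "WT", "SST") %in% names(table)), "missing_column",
            "columns GA, WT, SST required")
  if (is.null(mom)) mom <- compute_mom(table$concentration, table$concentration)
  df <- data.frame(y = log10(mom), GA = table$GA, WT = table$WT, SST = table$SST)
  X <- stats::model.matrix(~ GA + WT + SST, df)
  pt_assert(qr(X)$rank == ncol(X), "rank_deficient",
            "design matrix is rank deficient (collinear covariates)")
  fit <- stats::lm(y ~ GA + WT + SST, data = df)
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("intercept", "b_GA", "c_WT", "d_SST")
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(co)
  structure(list(coefficients = co, se = se, sigma = sm$sigma,
                 r_squared = sm$r.squared, fit = fit),
            class = "mom_fit")
}

#' Apply a log-linear MoM correction
#'
#' `corrected = mom / 10^(a + b*GA + c*WT + d*SST)`. With the published
#' placental FSTL3 coefficients the divisor's exponent at GA 36 wk is close
#' to zero, so corrected and uncorrected MoMs are comparable in scale.
#'
#' @param mom uncorrected MoM values.
#' @param GA,WT,SST covariates (recycled to the length of `mom`).
#' @param coefficients named vector or `mom_fit` coefficients: intercept,
#'   b_GA, c_WT, d_SST.
#' @return corrected MoM values.
#' @export
apply_mom_correction <- function(mom, GA, WT, SST, coefficients) {
  if (inherits(coefficients, "mom_fit")) coefficients <- coefficients$coefficients
  co <- coefficients
  pt_assert(all(is.finite(co)) && length(co) == 4L, "bad_coefficients",
            "need 4 finite coefficients (intercept, b_GA, c_WT, d_SST)")
  mom / 10^(co[[1L]] + co[[2L]] * GA + co[[3L]] * WT + co[[4L]] * SST)
}

#' Dichotomize values at a reference percentile
#'
#' The cutoff is the `pct`-th percentile of the reference subset via linear
#' interpolation of order statistics (`h = (n - 1) p + 1`, i.e. quantile
#' type 7); exceedance is strict (`value > cutoff`).
#'
#' @param values values to flag.
#' @param reference reference subset defining the cutoff (>= 2 values).
#' @param pct percentile in (0, 100) (default 97).
#' @return list with `cutoff` and logical `flags`.
#' @export
dichotomize_by_percentile <- function(values, reference, pct = 97) {
  pt_assert(pct > 0 && pct < 100, "bad_percentile", "pct must be in (0, 100)")
  pt_assert(length(reference) >= 2, "bad_shape", "reference needs >= 2 values")
  cutoff <- unname(stats::quantile(reference, pct / 100, type = 7))
  list(cutoff = cutoff, flags = values > cutoff)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a*d) / (b*c)` with a, b, c, d = exposed cases, unexposed cases,
#' exposed controls, unexposed controls; 95% CI on the log scale
#' (`exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`). Zero cells trigger
#' the Haldane-Anscombe 0.5 continuity correction, flagged in the result.
#'
#' @param a,b,c,d nonnegative integer cells.
#' @return list with `or`, `ci` (length 2), `continuity_corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  pt_assert(all(cells >= 0), "negative_cell", "cells must be >= 0")
  pt_assert(sum(cells) > 0, "empty_table", "all cells are zero")
  cc <- any(cells == 0)
  if (cc) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = or,
       ci = exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se),
       continuity_corrected = cc)
}

#' Per-group exceedance proportions with exact tests against control
#'
#' Summarizes a dichotomized biomarker: per-group exceedance counts and
#' proportions with exact binomial CIs, plus a two-sided Fisher exact P and
#' odds ratio for every case group against the control group.
#'
#' @param flags logical exceedance flags (from [dichotomize_by_percentile()]).
#' @param groups group label per subject.
#' @param control_label label of the control/comparison group.
#' @return data.frame, one row per group: `group`, `n`, `n_exceed`, `prop`,
#'   `ci_lo`, `ci_hi`, `or`, `or_lo`, `or_hi`, `fisher_p` (NA for control).
#' @export
group_exceedance_report <- function(flags, groups, control_label) {
  pt_assert(control_label %in% groups, "unknown_control",
            "control label '%s' not present", control_label)
  lev <- c(control_label, setdiff(unique(groups), control_label))
  ctl <- groups == control_label
  a0 <- sum(flags[ctl]); n0 <- sum(ctl)
  rows <- lapply(lev, function(g) {
    in_g <- groups == g
    a <- sum(flags[in_g]); n <- sum(in_g)
    bt <- stats::binom.test(a, n)
    row <- data.frame(group = g, n = n, n_exceed = a, prop = a / n,
                      ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2],
                      or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                      fisher_p = NA_real_, stringsAsFactors = FALSE)
    if (g != control_label) {
      orr <- odds_ratio_2x2(a, n - a, a0, n0 - a0)
      row$or <- orr$or; row$or_lo <- orr$ci[1]; row$or_hi <- orr$ci[2]
      row$fisher_p <- fisher_exact_2x2(matrix(c(a, n - a, a0, n0 - a0),
                                              2, 2, byrow = TRUE))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
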