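# Sample-level QC (decidual-contamination flagging) and priority-ordered
# greedy case-control matching with pair-exclusion rules.

#' Decidual-contamination marker panel
#'
#' Default markers are decidua-enriched genes whose joint elevation in a
#' chorionic-villus sample indicates maternal (decidual) tissue
#' contamination; the default rule flags a sample whose expression exceeds
#' `fold_threshold` times the cohort median for at least a quorum (majority)
#' of the panel.
#'
#' @param genes marker gene IDs.
#' @param fold_threshold fold-over-median threshold (> 1; default 20).
#' @param quorum number of markers that must fire (default: majority of the
#'   usable panel).
#' @return a named list of class `marker_panel`.
#' @export
marker_panel <- function(genes = c("IGFBP1", "OMD", "PRL", "RBP4",
                                   "KIAA1644", "RORB", "CHRDL1"),
                         fold_threshold = 20, quorum = NULL) {
  pt_assert(length(genes) > 0, "empty_input", "marker panel is empty")
  pt_assert(fold_threshold > 1, "bad_threshold", "fold_threshold must be > 1")
  structure(list(genes = genes, fold_threshold = fold_threshold,
                 quorum = quorum), class = "marker_panel")
}

#' Flag contaminated samples by marker fold-over-median
#'
#' For each sample and panel marker, the fold is the sample's value divided by
#' the cohort median of that marker; a sample is flagged iff the fold reaches
#' the threshold for at least `quorum` markers. Markers with a zero cohort
#' median (fold undefined) are skipped and reported. The rule is invariant to
#' sample order and to uniform rescaling of the matrix.
#'
#' @param x an [expression_matrix()] containing the panel genes.
#' @param panel a [marker_panel()].
#' @return list with `flagged` (sample IDs), `folds` (marker x sample matrix),
#'   `skipped_markers`.
#' @export
flag_contaminated_samples <- function(x, panel = marker_panel()) {
  stopifnot(inherits(x, "expr_matrix"))
  pt_assert(all(panel$genes %in% rownames(x$values)), "missing_marker",
            "panel gene(s) missing from the matrix: %s",
            paste(setdiff(panel$genes, rownames(x$values)), collapse = ", "))
  v <- x$values[panel$genes, , drop = FALSE]
  med <- apply(v, 1, stats::median)
  skipped <- panel$genes[med == 0]
  usable <- panel$genes[med > 0]
  pt_assert(length(usable) > 0, "degenerate_panel", "all marker medians are zero")
  folds <- sweep(v[usable, , drop = FALSE], 1, med[usable], "/")
  quorum <- panel$quorum %||% ceiling(length(usable) / 2)
  n_fire <- colSums(folds >= panel$fold_threshold)
  list(flagged = colnames(folds)[n_fire >= quorum], folds = folds,
       skipped_markers = skipped)
}

#' Matching criteria in priority order
#'
#' Defaults mirror a seven-characteristic priority order for placental
#' case-control matching: presence of labor (exact), gestational age
#' (nearest), fetal sex (exact), caesarean section (exact), smoking status
#' (exact), maternal BMI (nearest), maternal age (nearest).
#'
#' @param covariate,kind,tolerance vectors describing each criterion in
#'   priority order; `kind` is `"exact"` or `"nearest"`; `tolerance` is the
#'   distance granularity within which nearest candidates tie (0 = exact
#'   comparison).
#' @return data.frame of class `match_criteria`.
#' @export
match_criteria <- function(covariate = c("labor", "GA", "sex", "caesarean",
                                         "smoking", "BMI", "age"),
                           kind = c("exact", "nearest", "exact", "exact",
                                    "exact", "nearest", "nearest"),
                           tolerance = 0) {
  pt_assert(length(covariate) > 0, "empty_input", "no criteria")
  pt_assert(all(kind %in% c("exact", "nearest")), "bad_kind",
            "kind must be exact or nearest")
  df <- data.frame(covariate = covariate, kind = rep_len(kind, length(covariate)),
                   tolerance = rep_len(tolerance, length(covariate)),
                   stringsAsFactors = FALSE)
  class(df) <- c("match_criteria", "data.frame")
  df
}

#' Greedy priority-ordered case-control matching
#'
#' Cases are processed in input order. For each case, candidate controls are
#' filtered by the exact criteria in priority order; if no candidate remains,
#' exact criteria are relaxed starting from the LOWEST priority until a
#' candidate exists. Among the candidates, the control minimizing the
#' lexicographic vector of nearest-criterion distances (in priority order,
#' with ties within `tolerance` broken by the next criterion, then by control
#' ID) is chosen and removed from the pool. Each control is used at most once.
#'
#' @param cases,controls data.frames with a `sample_id` column and the
#'   criterion covariates.
#' @param criteria a [match_criteria()].
#' @return data.frame of pairs: `case_id`, `control_id`, `relaxed` (comma-
#'   separated relaxed exact criteria, `""` if none), plus one
#'   `dist_<covariate>` column per nearest criterion; attribute
#'   `"unmatched_cases"` lists cases left without a control.
#' @export
match_case_control <- function(cases, controls, criteria = match_criteria()) {
  pt_assert(nrow(controls) > 0, "empty_pool", "no controls available")
  for (cv in criteria$covariate) {
    pt_assert(cv %in% names(cases) && cv %in% names(controls), "missing_column",
              "covariate '%s' missing", cv)
  }
  exact_idx <- which(criteria$kind == "exact")
  nearest_idx <- which(criteria$kind == "nearest")
  pool <- controls
  pairs <- list(); unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, , drop = FALSE]
    if (nrow(pool) == 0) { unmatched <- c(unmatched, cs$sample_id); next }
    # enforce exact criteria; relax lowest-priority ones until candidates exist
    relaxed <- character(0)
    enforce <- exact_idx
    repeat {
      cand <- rep(TRUE, nrow(pool))
      for (j in enforce)
        cand <- cand & pool[[criteria$covariate[j]]] == cs[[criteria$covariate[j]]]
      if (any(cand) || length(enforce) == 0) break
      dropped <- enforce[length(enforce)]      # lowest priority first
      relaxed <- c(criteria$covariate[dropped], relaxed)
      enforce <- enforce[-length(enforce)]
    }
    if (!any(cand)) { unmatched <- c(unmatched, cs$sample_id); next }
    cand_rows <- which(cand)
    # lexicographic nearest-distance selection in priority order
    best <- cand_rows
    dists <- matrix(0, nrow = length(cand_rows), ncol = length(nearest_idx))
    for (jj in seq_along(nearest_idx)) {
      j <- nearest_idx[jj]
      dists[, jj] <- abs(pool[[criteria$covariate[j]]][cand_rows] -
                           cs[[criteria$covariate[j]]])
    }
    sel <- seq_along(cand_rows)
    for (jj in seq_along(nearest_idx)) {
      d <- dists[sel, jj]
      tol <- criteria$tolerance[nearest_idx[jj]]
      sel <- sel[d <= min(d) + tol]
      if (length(sel) == 1L) break
    }
    if (length(sel) > 1L)  # final deterministic tie-break
      sel <- sel[order(pool$sample_id[cand_rows[sel]])][1L]
    chosen <- cand_rows[sel]
    row <- data.frame(case_id = cs$sample_id, control_id = pool$sample_id[chosen],
                      relaxed = paste(relaxed, collapse = ","),
                      stringsAsFactors = FALSE)
    for (jj in seq_along(nearest_idx))
      row[[paste0("dist_", criteria$covariate[nearest_idx[jj]])]] <-
        abs(pool[[criteria$covariate[nearest_idx[jj]]]][chosen] -
              cs[[criteria$covariate[nearest_idx[jj]]]])
    pairs[[length(pairs) + 1L]] <- row
    pool <- pool[-chosen, , drop = FALSE]
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               relaxed = character(0))
  rownames(out) <- NULL
  attr(out, "unmatched_cases") <- unmatched
  out
}

#' Exclude matched pairs by rule
#'
#' Removes a pair iff any enabled rule fires, and logs which rule fired.
#' Supported rules: `sex_mismatch` (case and control fetal sex differ),
#' `contamination` (either member flagged), `batch` (either member flagged),
#' and `comorbidities` (the case carries one of the listed comorbidity
#' labels, e.g. a growth-restriction case that also had preeclampsia or
#' hypertension).
#'
#' @param pairs data.frame with per-pair columns as needed by the enabled
#'   rules: `case_sex`/`control_sex`, `contamination_flag`, `batch_flag`,
#'   `case_comorbidities` (comma-separated labels).
#' @param rules named list: `sex_mismatch` (logical), `contamination`
#'   (logical), `batch` (logical), `comorbidities` (character vector of
#'   disqualifying labels, or `NULL`).
#' @return list with `retained` (pair rows kept) and `log` (data.frame
#'   pair index, rule fired).
#' @export
exclude_mismatched_pairs <- function(pairs,
                                     rules = list(sex_mismatch = TRUE,
                                                  contamination = TRUE,
                                                  batch = FALSE,
                                                  comorbidities = NULL)) {
  n <- nrow(pairs)
  fired <- rep(NA_character_, n)
  maybe <- function(cond, label) {
    hit <- is.na(fired) & cond
    fired[hit] <<- label
  }
  if (isTRUE(rules$sex_mismatch) && all(c("case_sex", "control_sex") %in% names(pairs)))
    maybe(pairs$case_sex != pairs$control_sex, "sex_mismatch")
  if (isTRUE(rules$contamination) && "contamination_flag" %in% names(pairs))
    maybe(pairs$contamination_flag, "contamination")
  if (isTRUE(rules$batch) && "batch_flag" %in% names(pairs))
    maybe(pairs$batch_flag, "batch")
  if (!is.null(rules$comorbidities) && "case_comorbidities" %in% names(pairs)) {
    labels <- strsplit(ifelse(is.na(pairs$case_comorbidities), "",
                              pairs$case_comorbidities), ",")
    hit <- vapply(labels, function(l) any(trimws(l) %in% rules$comorbidities),
                  logical(1))
    maybe(hit, "comorbidity")
  }
  keep <- is.na(fired)
  list(retained = pairs[keep, , drop = FALSE],
       log = data.frame(pair = which(!keep), rule = fired[!keep],
                        stringsAsFactors = FALSE))
}
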