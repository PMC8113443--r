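# Pipeline driver: a YAML/list config selects stages and input files; the
# driver runs each stage over the referenced inputs and returns (or writes) a
# deterministic JSON report with the seed and thresholds echoed.

PIPELINE_STAGES <- c("complexity", "circ", "biomarker")

#' Pipeline configuration
#'
#' @param stages character vector of stage names; known stages are
#'   `"complexity"` (expression TSV -> TA50, class table, top-1% share),
#'   `"circ"` (circ count TSV + poly-A ID list -> prevalence filter and host
#'   census) and `"biomarker"` (biomarker TSV -> MoM correction, 97th
#'   percentile dichotomization, odds ratios).
#' @param inputs named list of stage input paths: `expression` (TSV;
#'   `expression_unit` declares its unit), `circ_counts` (TSV with a
#'   `host_gene` column), `polya_ids` (one ID per line), `biomarker` (TSV
#'   with concentration/GA/WT/SST/subcohort/group columns).
#' @param thresholds named list overriding stage defaults
#'   (`min_presence_frac`, `pct`, `top_fraction`, ...).
#' @param seed integer seed recorded in every report.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages, inputs = list(), thresholds = list(),
                            seed = 1L) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  pt_assert(length(unknown) == 0, "unknown_stage", "unknown stage(s): %s",
            paste(unknown, collapse = ", "))
  structure(list(stages = stages, inputs = inputs, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields `stages`, `inputs`, `thresholds`, `seed`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(stages = unlist(y$stages),
                  inputs = y$inputs %||% list(),
                  thresholds = y$thresholds %||% list(),
                  seed = y$seed %||% 1L)
}

stage_input <- function(config, key, stage) {
  p <- config$inputs[[key]]
  pt_assert(!is.null(p), "missing_input", "stage '%s' needs input '%s'", stage, key)
  pt_assert(file.exists(p), "missing_input", "input file not found: %s", p)
  p
}

run_stage_complexity <- function(config) {
  em <- read_expression_matrix(stage_input(config, "expression", "complexity"),
                               unit = config$inputs$expression_unit %||% "RPKM")
  ab <- rowMeans(em$values)
  top_frac <- config$thresholds$top_fraction %||% 0.01
  t50 <- ta50(ab)
  out <- list(n_features = nrow(em$values),
              ta50_count = t50$count, ta50_fraction = t50$fraction,
              top_fraction = top_frac,
              top_fraction_share = top_fraction_share(ab, top_frac))
  if (!is.null(em$feature_meta$biotype))
    out$class_table <- abundance_class_table(ab, em$feature_meta$biotype,
                                             allow_unlabeled = TRUE)
  out
}

run_stage_circ <- function(config) {
  df <- utils::read.delim(stage_input(config, "circ_counts", "circ"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  host <- if ("host_gene" %in% names(df)) df$host_gene else NULL
  counts <- as.matrix(df[setdiff(names(df), c("circ_id", "host_gene"))])
  rownames(counts) <- df$circ_id
  polya <- character(0)
  if (!is.null(config$inputs$polya_ids))
    polya <- readLines(stage_input(config, "polya_ids", "circ"))
  ds <- circ_dataset(counts, host_gene_start = host, host_gene_end = host,
                     polya_ids = polya)
  frac <- config$thresholds$min_presence_frac %||% 0.3
  fl <- filter_circ_candidates(ds, min_presence_frac = frac)
  census <- host_gene_circ_census(ds$host_gene_start[fl$kept],
                                  config$thresholds$min_circ_per_gene %||% 10)
  list(n_input = nrow(counts), min_presence_frac = frac,
       n_retained = length(fl$retained),
       n_polya_removed = sum(fl$reasons == "polyA_control"),
       census = census)
}

run_stage_biomarker <- function(config) {
  tab <- utils::read.delim(stage_input(config, "biomarker", "biomarker"),
                           stringsAsFactors = FALSE)
  ref <- tab[as.logical(tab$subcohort), , drop = FALSE]
  mom_all <- compute_mom(tab$concentration, ref$concentration)
  fit <- fit_mom_correction(ref)
  corrected <- apply_mom_correction(mom_all, tab$GA, tab$WT, tab$SST, fit)
  pct <- config$thresholds$pct %||% 97
  di <- dichotomize_by_percentile(corrected,
                                  corrected[as.logical(tab$subcohort)], pct)
  rep_tab <- group_exceedance_report(di$flags, tab$group,
                                     config$thresholds$control_label %||% "CTL")
  list(n_subjects = nrow(tab), pct = pct, cutoff = di$cutoff,
       coefficients = as.list(fit$coefficients), report = rep_tab)
}

#' Run the configured pipeline stages
#'
#' Executes each configured stage over its inputs and assembles one report
#' section per stage, with the seed and thresholds echoed. The same config
#' and seed produce a byte-identical report (and JSON file, when `out_json`
#' is given).
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_json optional path; the report is serialized there as JSON.
#' @return the report list, invisibly when written to file.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  runners <- list(complexity = run_stage_complexity,
                  circ = run_stage_circ,
                  biomarker = run_stage_biomarker)
  report <- list(seed = config$seed, thresholds = config$thresholds,
                 stages = list())
  for (st in config$stages) {
    section <- tryCatch(runners[[st]](config), error = function(e) {
      pt_stop("stage_failure", "stage '%s' failed: %s", st, conditionMessage(e))
    })
    report$stages[[st]] <- section
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
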