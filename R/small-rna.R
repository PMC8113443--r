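# Interval-overlap cascade for collapsed small-RNA reads: class-wise
# exclusion and quantification, novel-miRNA consensus filtering, novel-locus
# discovery and read-length summaries. All operations are strand-aware.

CATALOG_CLASSES <- c("mature_mirna", "precursor_mirna", "novel_mirna",
                     "pirna", "trna", "sncrna", "exon")

#' Annotation catalog for small-RNA classification
#'
#' @param ... named [interval_set()]s; names must come from the fixed class
#'   vocabulary: mature_mirna, precursor_mirna, novel_mirna, pirna, trna,
#'   sncrna, exon.
#' @return a named list of class `annotation_catalog`.
#' @export
annotation_catalog <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.null(names(sets)) && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "interval_set")) sets <- sets[[1L]]
  pt_assert(length(sets) > 0 && !is.null(names(sets)), "bad_catalog",
            "catalog sets must be named")
  bad <- setdiff(names(sets), CATALOG_CLASSES)
  pt_assert(length(bad) == 0, "unknown_class", "unknown catalog class(es): %s",
            paste(bad, collapse = ", "))
  for (s in sets) stopifnot(inherits(s, "interval_set"))
  structure(sets, class = "annotation_catalog")
}

# strand-aware overlap pairs with overlap widths; x, y are interval_sets
overlap_pairs <- function(x, y, min_width = 1L) {
  gx <- as_granges(x); gy <- as_granges(y)
  # disjoint chromosome sets are a legitimate no-overlap case, not a warning
  h <- suppressWarnings(GenomicRanges::findOverlaps(gx, gy,
                                                    minoverlap = min_width,
                                                    ignore.strand = FALSE))
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  w <- pmin(x$end[qi], y$end[si]) - pmax(x$start[qi], y$start[si])
  data.frame(query = qi, subject = si, overlap = w)
}

#' Quantify collapsed reads over annotated loci (30% rule)
#'
#' A read contributes its full multiplicity to a locus iff it lies on the
#' same strand and the overlap covers at least `min_frac_of_locus` of the
#' locus length (the annotation side, mirroring `intersectBed -s -f 0.3` with
#' the annotation as the fraction-bearing operand). A read may count toward
#' several overlapping loci.
#'
#' @param reads an [interval_set()] with a `multiplicity` column.
#' @param loci an [interval_set()] of annotated loci.
#' @param min_frac_of_locus required overlap fraction of the locus, in (0, 1].
#' @return data.frame (`id`, `count`) over all loci; 0 where no read qualifies.
#' @export
quantify_by_overlap <- function(reads, loci, min_frac_of_locus = 0.3) {
  pt_assert(min_frac_of_locus > 0 && min_frac_of_locus <= 1, "bad_fraction",
            "min_frac_of_locus must be in (0, 1]")
  pt_assert(all(reads$strand %in% c("+", "-")) && all(loci$strand %in% c("+", "-")),
            "missing_strand", "strands must be defined on both reads and loci")
  mult <- reads$multiplicity
  if (is.null(mult)) mult <- rep(1L, nrow(reads))
  counts <- stats::setNames(numeric(nrow(loci)), loci$id)
  if (nrow(reads) && nrow(loci)) {
    op <- overlap_pairs(reads, loci)
    need <- min_frac_of_locus * (loci$end[op$subject] - loci$start[op$subject])
    op <- op[op$overlap >= need - 1e-9, , drop = FALSE]
    if (nrow(op)) {
      agg <- tapply(mult[op$query], loci$id[op$subject], sum)
      counts[names(agg)] <- agg
    }
  }
  data.frame(id = loci$id, count = as.numeric(counts), stringsAsFactors = FALSE)
}

#' Classification cascades
#'
#' A cascade is an ordered list of stages; each stage claims reads that
#' overlap its catalog class on the same strand (by at least 1 bp, or by the
#' 30% of-locus rule for quantification stages). Each read goes to the first
#' stage that claims it; unclaimed reads end in `"unassigned"`. The presets
#' mirror the exclusion orders used for placental small-RNA data: the piRNA
#' stage excludes only mature miRNAs; the sncRNA stage also excludes precursor
#' miRNAs, piRNAs and tRNAs; the novel stage additionally excludes annotated
#' novel miRNAs and exons.
#'
#' @return list of stages, each `list(class =, rule = "any"|"frac", min_frac =)`.
#' @export
cascade_pirna <- function() list(
  list(class = "mature_mirna", rule = "any"),
  list(class = "pirna", rule = "frac", min_frac = 0.3))

#' @rdname cascade_pirna
#' @export
cascade_sncrna <- function() list(
  list(class = "mature_mirna", rule = "any"),
  list(class = "precursor_mirna", rule = "any"),
  list(class = "pirna", rule = "any"),
  list(class = "trna", rule = "any"),
  list(class = "sncrna", rule = "frac", min_frac = 0.3))

#' @rdname cascade_pirna
#' @export
cascade_novel <- function() list(
  list(class = "mature_mirna", rule = "any"),
  list(class = "precursor_mirna", rule = "any"),
  list(class = "novel_mirna", rule = "any"),
  list(class = "pirna", rule = "any"),
  list(class = "exon", rule = "any"))

#' Classify collapsed reads through an exclusion cascade
#'
#' @param reads an [interval_set()] with multiplicities.
#' @param catalog an [annotation_catalog()].
#' @param cascade an ordered stage list (see [cascade_pirna()]).
#' @return list with `assignment` (per-read class, `"unassigned"` for
#'   unclaimed), `class_multiplicity` (summed multiplicity per class; conserves
#'   the input total) and `locus_counts` (per-locus counts for quantification
#'   stages, computed over the reads surviving to that stage).
#' @export
classify_reads <- function(reads, catalog, cascade = cascade_pirna()) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  for (st in cascade)
    pt_assert(st$class %in% CATALOG_CLASSES, "unknown_class",
              "unknown class '%s' in cascade", st$class)
  n <- nrow(reads)
  mult <- reads$multiplicity
  if (is.null(mult)) mult <- rep(1L, n)
  assignment <- rep("unassigned", n)
  available <- rep(TRUE, n)
  locus_counts <- list()
  for (st in cascade) {
    ann <- catalog[[st$class]]
    if (is.null(ann) || nrow(ann) == 0 || !any(available)) next
    idx <- which(available)
    sub <- reads[idx, , drop = FALSE]
    op <- overlap_pairs(sub, ann)
    if (identical(st$rule, "frac")) {
      need <- (st$min_frac %||% 0.3) * (ann$end[op$subject] - ann$start[op$subject])
      op <- op[op$overlap >= need - 1e-9, , drop = FALSE]
      locus_counts[[st$class]] <- quantify_by_overlap(
        sub, ann, min_frac_of_locus = st$min_frac %||% 0.3)
    }
    claimed <- idx[unique(op$query)]
    assignment[claimed] <- st$class
    available[claimed] <- FALSE
  }
  cm <- tapply(mult, assignment, sum)
  list(assignment = assignment,
       class_multiplicity = cm[order(names(cm))],
       locus_counts = locus_counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reciprocal-overlap consensus filter for novel miRNA candidates
#'
#' A primary candidate survives iff some interval in any support set overlaps
#' it on the same strand by at least `reciprocal_frac` of the candidate's
#' length AND of the support interval's length (`intersectBed -s -f 0.3 -r`).
#'
#' @param primary candidate [interval_set()].
#' @param supports list of support [interval_set()]s (independent predictors).
#' @param reciprocal_frac required reciprocal fraction in (0, 1].
#' @return the supported subset of `primary`.
#' @export
consensus_novel_mirna <- function(primary, supports, reciprocal_frac = 0.3) {
  pt_assert(reciprocal_frac > 0 && reciprocal_frac <= 1, "bad_fraction",
            "reciprocal_frac must be in (0, 1]")
  keep <- rep(FALSE, nrow(primary))
  len_p <- primary$end - primary$start
  for (sup in supports) {
    if (nrow(sup) == 0 || !any(!keep)) next
    op <- overlap_pairs(primary, sup)
    if (!nrow(op)) next
    ok <- op$overlap >= reciprocal_frac * len_p[op$query] - 1e-9 &
      op$overlap >= reciprocal_frac * (sup$end[op$subject] - sup$start[op$subject]) - 1e-9
    keep[unique(op$query[ok])] <- TRUE
  }
  primary[keep, , drop = FALSE]
}

#' Discover novel small-RNA loci from collapsed reads
#'
#' Reads overlapping any exclusion class (1 bp, same strand) are removed;
#' reads with multiplicity below `min_multiplicity` are removed (multiplicity
#' of the collapsed read, not positional pileup); the survivors are merged
#' transitively when they overlap by at least 1 bp on the same strand, and
#' each merged locus reports the summed multiplicity of its reads.
#'
#' @param reads an [interval_set()] with multiplicities.
#' @param exclusion an [annotation_catalog()] or single [interval_set()].
#' @param min_multiplicity minimum collapsed-read multiplicity (>= 1).
#' @return an [interval_set()] of merged loci with `multiplicity` = summed
#'   read multiplicity.
#' @export
discover_novel_smallrna_loci <- function(reads, exclusion, min_multiplicity = 10) {
  pt_assert(min_multiplicity >= 1, "bad_multiplicity", "min_multiplicity must be >= 1")
  excl <- if (inherits(exclusion, "interval_set")) list(exclusion) else exclusion
  keep <- rep(TRUE, nrow(reads))
  for (ann in excl) {
    if (is.null(ann) || nrow(ann) == 0) next
    op <- overlap_pairs(reads, ann)
    keep[unique(op$query)] <- FALSE
  }
  mult <- reads$multiplicity %||% rep(1L, nrow(reads))
  keep <- keep & mult >= min_multiplicity
  surv <- reads[keep, , drop = FALSE]
  if (nrow(surv) == 0)
    return(interval_set(character(0), integer(0), integer(0), multiplicity = integer(0)))
  gr <- as_granges(surv)
  # min.gapwidth = 0: merge only true >= 1 bp overlaps, never book-ended runs
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = FALSE)
  h <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = FALSE)
  msum <- tapply(surv$multiplicity[S4Vectors::queryHits(h)],
                 S4Vectors::subjectHits(h), sum)
  interval_set(as.character(GenomicRanges::seqnames(merged)),
               GenomicRanges::start(merged) - 1L, GenomicRanges::end(merged),
               id = sprintf("novel_%04d", seq_along(merged)),
               strand = as.character(GenomicRanges::strand(merged)),
               multiplicity = as.integer(msum[as.character(seq_along(merged))]))
}

#' Locus counts at sample-frequency thresholds
#'
#' For each threshold fraction f, counts loci present in at least
#' `presence_min_count(n_samples, f)` samples. Counts are nonincreasing in f.
#'
#' @param presence logical (or 0/1) matrix, loci x samples.
#' @param fractions presence fractions to evaluate (default 0.3 and 1.0).
#' @return data.frame with columns `fraction`, `min_samples`, `n_loci`.
#' @export
sample_frequency_table <- function(presence, fractions = c(0.3, 1.0)) {
  presence <- as.matrix(presence)
  pt_assert(ncol(presence) >= 1, "empty_input", "no samples")
  n <- ncol(presence)
  hits <- rowSums(presence > 0)
  data.frame(fraction = fractions,
             min_samples = vapply(fractions, presence_min_count,
                                  integer(1), n_samples = n),
             n_loci = vapply(fractions, function(f)
               sum(hits >= presence_min_count(n, f)), numeric(1)))
}

#' Multiplicity-weighted read-length distribution
#'
#' @param reads an [interval_set()] with multiplicities; read length is
#'   `end - start`.
#' @return list with `histogram` (data.frame length/weight) and `mode`
#'   (smallest length on ties).
#' @export
read_length_distribution <- function(reads) {
  pt_assert(nrow(reads) > 0, "empty_input", "no reads")
  len <- reads$end - reads$start
  mult <- reads$multiplicity %||% rep(1L, nrow(reads))
  w <- tapply(mult, len, sum)
  hist <- data.frame(length = as.integer(names(w)), weight = as.numeric(w))
  hist <- hist[order(hist$length), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist,
       mode = hist$length[which.max(hist$weight)])  # which.max: first ( = smallest) on ties
}
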