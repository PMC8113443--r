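# Seeded synthetic-data generators with planted ground truth. Each generator
# is a pure function of its parameters and seed, and returns the dataset
# together with a `truth` record describing everything that was planted.
# These emulate the statistical structure of a large placental
# total/small-RNA transcriptome cohort (restricted-access raw data), not
# read-level sequencing realism.

truth_record <- function(generator, seed, ...) {
  list(generator = generator, seed = seed, params = list(...))
}

#' Simulate a heavy-tailed transcript abundance profile
#'
#' Abundances are log-normal(0, sigma^2), rescaled to an RPKM-like range, with
#' biotype labels drawn from the given mix. Larger sigma gives a more skewed
#' transcriptome (smaller TA50). `sigma = 0` gives a uniform profile.
#'
#' @param n_features number of transcripts (>= 1).
#' @param biotype_mix named proportions summing to 1.
#' @param lognormal_sigma log-scale SD (>= 0).
#' @param seed RNG seed.
#' @param scale multiplicative scale applied after sampling (default 10).
#' @return list with `matrix` (single-sample [expression_matrix()], RPKM) and
#'   `truth`.
#' @export
simulate_abundance_profile <- function(n_features,
                                       biotype_mix = c(protein_coding = 0.6,
                                                       lincRNA = 0.2,
                                                       pseudogene = 0.2),
                                       lognormal_sigma = 2, seed = 1L,
                                       scale = 10) {
  pt_assert(n_features >= 1, "bad_n", "n_features must be >= 1")
  pt_assert(lognormal_sigma >= 0, "bad_sigma", "sigma must be >= 0")
  pt_assert(abs(sum(biotype_mix) - 1) < 1e-8, "bad_mix",
            "biotype_mix must sum to 1")
  set.seed(seed)
  ab <- scale * exp(stats::rnorm(n_features, 0, lognormal_sigma))
  biotype <- sample(names(biotype_mix), n_features, replace = TRUE,
                    prob = biotype_mix)
  ids <- sprintf("tx%06d", seq_len(n_features))
  vals <- matrix(ab, ncol = 1, dimnames = list(ids, "sample1"))
  em <- expression_matrix(vals, "RPKM",
                          feature_meta = data.frame(biotype = biotype))
  list(matrix = em,
       truth = truth_record("abundance_profile", seed,
                            n_features = n_features, sigma = lognormal_sigma,
                            biotype = stats::setNames(biotype, ids)))
}

#' Simulate a gene x tissue TPM panel with planted enriched genes
#'
#' Background genes are near-uniform across tissues (multiplicative log-normal
#' noise around a per-gene baseline). Each tissue receives
#' `n_enriched_per_tissue` planted genes constructed to pass the strict
#' enrichment criteria (Tau > 0.99, TPM > 1, > 100x the mean of the remaining
#' tissues): high expression in the home tissue and near-zero elsewhere.
#'
#' @param n_genes,n_tissues panel dimensions (`n_tissues >= 2`).
#' @param n_enriched_per_tissue planted enriched genes per tissue.
#' @param expr_params list: `bg_mean_log`, `bg_sd_log` (baseline log-normal),
#'   `noise_sd_log` (tissue noise), `enriched_tpm` (home-tissue level),
#'   `leak_frac` (off-tissue level as a fraction of home, default 5e-4).
#' @param seed RNG seed.
#' @return list with `panel` (gene x tissue TPM-scale matrix) and `truth`
#'   (`enriched`: data.frame gene, tissue).
#' @export
simulate_tissue_panel <- function(n_genes, n_tissues, n_enriched_per_tissue,
                                  expr_params = list(), seed = 1L) {
  pt_assert(n_tissues >= 2, "bad_n", "Tau needs >= 2 tissues")
  pt_assert(n_enriched_per_tissue * n_tissues <= n_genes, "infeasible",
            "more planted genes than n_genes")
  p <- utils::modifyList(list(bg_mean_log = 1, bg_sd_log = 1,
                              noise_sd_log = 0.2, enriched_tpm = 50,
                              leak_frac = 5e-4), expr_params)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  base <- exp(stats::rnorm(n_genes, p$bg_mean_log, p$bg_sd_log))
  mat <- base * exp(matrix(stats::rnorm(n_genes * n_tissues, 0, p$noise_sd_log),
                           n_genes, n_tissues))
  dimnames(mat) <- list(genes, tissues)
  n_enr <- n_enriched_per_tissue * n_tissues
  enr_gene <- genes[seq_len(n_enr)]
  enr_tissue <- rep(tissues, each = n_enriched_per_tissue)
  for (i in seq_len(n_enr)) {
    home <- p$enriched_tpm * exp(stats::rnorm(1, 0, 0.2))
    row <- home * p$leak_frac * stats::runif(n_tissues)
    row[match(enr_tissue[i], tissues)] <- home
    mat[enr_gene[i], ] <- row
  }
  list(panel = mat,
       truth = truth_record("tissue_panel", seed,
                            enriched = data.frame(gene = enr_gene,
                                                  tissue = enr_tissue,
                                                  stringsAsFactors = FALSE)))
}

#' Simulate two matched case-control cohorts with planted fold changes
#'
#' Two paired cohorts (sizes mirroring an 82-pair and a 40-pair phenotype
#' design) share one feature space. Control values are log-normal around a
#' per-feature baseline; case values are multiplied by `2^effect_log2` on the
#' planted features of that cohort. The planted sets overlap by
#' `round(overlap_frac * min set size)` features.
#'
#' @param n_pairs_a,n_pairs_b pairs per cohort (defaults 82 and 40).
#' @param n_features feature-space size.
#' @param planted_up_a,planted_up_b planted set sizes.
#' @param overlap_frac planted-set overlap fraction in \[0, 1\].
#' @param effect_log2 log2 effect size on planted features.
#' @param noise_sigma log-scale noise SD.
#' @param seed RNG seed.
#' @return list with `matrix` ([expression_matrix()], RPM-like, all samples),
#'   `cohort_a`, `cohort_b` (data.frames sample_id, group, pair_id, role),
#'   and `truth` (planted sets and shared features).
#' @export
simulate_paired_cohort <- function(n_pairs_a = 82, n_pairs_b = 40,
                                   n_features = 1000,
                                   planted_up_a = 50, planted_up_b = 50,
                                   overlap_frac = 0.5, effect_log2 = 1,
                                   noise_sigma = 0.25, seed = 1L) {
  pt_assert(planted_up_a <= n_features && planted_up_b <= n_features,
            "infeasible", "planted sets must fit within n_features")
  pt_assert(overlap_frac >= 0 && overlap_frac <= 1, "bad_fraction",
            "overlap_frac must be in [0, 1]")
  set.seed(seed)
  ids <- sprintf("tx%05d", seq_len(n_features))
  n_shared <- round_half_up(overlap_frac * min(planted_up_a, planted_up_b))
  set_a <- ids[seq_len(planted_up_a)]
  set_b <- ids[c(seq_len(n_shared),
                 planted_up_a + seq_len(planted_up_b - n_shared))]
  base <- exp(stats::rnorm(n_features, 2, 1))
  gen_cohort <- function(n_pairs, planted, label) {
    eff <- ifelse(ids %in% planted, 2^effect_log2, 1)
    noise <- function(n) exp(matrix(stats::rnorm(n_features * n, 0, noise_sigma),
                                    n_features, n))
    ctl <- base * noise(n_pairs)
    cas <- base * eff * noise(n_pairs)
    colnames(ctl) <- sprintf("%s_ctl%03d", label, seq_len(n_pairs))
    colnames(cas) <- sprintf("%s_case%03d", label, seq_len(n_pairs))
    list(ctl = ctl, cas = cas)
  }
  a <- gen_cohort(n_pairs_a, set_a, "A")
  b <- gen_cohort(n_pairs_b, set_b, "B")
  vals <- cbind(a$cas, a$ctl, b$cas, b$ctl)
  rownames(vals) <- ids
  meta <- function(label, group, n_pairs) {
    data.frame(sample_id = c(sprintf("%s_case%03d", label, seq_len(n_pairs)),
                             sprintf("%s_ctl%03d", label, seq_len(n_pairs))),
               group = rep(c(group, "CTL"), each = n_pairs),
               pair_id = rep(sprintf("%s_p%03d", label, seq_len(n_pairs)), 2),
               role = rep(c("case", "control"), each = n_pairs),
               stringsAsFactors = FALSE)
  }
  list(matrix = expression_matrix(vals, "RPM"),
       cohort_a = meta("A", "PE", n_pairs_a),
       cohort_b = meta("B", "FGR", n_pairs_b),
       truth = truth_record("paired_cohort", seed,
                            planted_a = set_a, planted_b = set_b,
                            shared = intersect(set_a, set_b),
                            effect_log2 = effect_log2,
                            noise_sigma = noise_sigma))
}

#' Simulate collapsed small-RNA reads over an annotation catalog
#'
#' Emits strand-consistent collapsed reads inside each catalog locus, with
#' lengths peaked at `length_mode` nt (the piRNA-range mode seen after miRNA
#' exclusion in placental small-RNA data), plus planted novel reads at loci
#' disjoint from the catalog with caller-specified multiplicities.
#'
#' @param catalog an [annotation_catalog()] of source loci.
#' @param reads_per_locus reads emitted per catalog locus.
#' @param planted_novel optional [interval_set()] with a `multiplicity`
#'   column: novel loci to plant (must not overlap the catalog).
#' @param length_mode modal read length in nt (default 28).
#' @param multiplicity_mean mean of the (1 + Poisson) multiplicity draw.
#' @param seed RNG seed.
#' @return list with `reads` (an [interval_set()] with multiplicities) and
#'   `truth`.
#' @export
simulate_small_rna_reads <- function(catalog, reads_per_locus = 5,
                                     planted_novel = NULL, length_mode = 28,
                                     multiplicity_mean = 4, seed = 1L) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!is.null(planted_novel)) {
    for (ann in catalog) {
      if (nrow(ann) == 0) next
      op <- overlap_pairs(planted_novel, ann)
      pt_assert(nrow(op) == 0, "planted_overlap",
                "planted novel locus overlaps the exclusion catalog")
    }
  }
  set.seed(seed)
  rows <- list()
  for (cls in names(catalog)) {
    ann <- catalog[[cls]]
    for (i in seq_len(nrow(ann))) {
      for (r in seq_len(reads_per_locus)) {
        locus_len <- ann$end[i] - ann$start[i]
        # an atom at the mode plus discretized Gaussian spread keeps the
        # length distribution genuinely peaked at length_mode
        len <- if (stats::runif(1) < 0.5) length_mode else
          round_half_up(stats::rnorm(1, length_mode, 2))
        len <- max(18L, min(len, 35L, locus_len))
        off <- sample.int(max(1L, locus_len - len + 1L), 1L) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ann$chrom[i], start = ann$start[i] + off,
          end = ann$start[i] + off + len, strand = ann$strand[i],
          multiplicity = 1L + stats::rpois(1, multiplicity_mean - 1),
          source = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(planted_novel)) {
    for (i in seq_len(nrow(planted_novel)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = planted_novel$chrom[i], start = planted_novel$start[i],
        end = planted_novel$end[i], strand = planted_novel$strand[i],
        multiplicity = planted_novel$multiplicity[i], source = "novel",
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  reads <- interval_set(df$chrom, df$start, df$end,
                        id = sprintf("read%05d", seq_len(nrow(df))),
                        strand = df$strand, multiplicity = df$multiplicity)
  reads$source <- df$source
  list(reads = reads,
       truth = truth_record("small_rna_reads", seed,
                            length_mode = length_mode,
                            source = df$source,
                            planted_novel = planted_novel))
}

# zero-truncated Poisson via the inverse-CDF trick (deterministic in the
# uniform stream)
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate a circRNA back-splice-junction dataset
#'
#' Per-sample presence is Bernoulli (per-circ probability); BSJ counts are
#' zero-truncated Poisson(`bsj_mean`) where present. The first
#' `n_false_positive` circRNAs are also emitted in the companion poly-A
#' negative-control ID set (planted false positives). Each circ carries one
#' host gene at both ends and matched linear-junction counts.
#'
#' @param n_circ,n_samples dataset dimensions.
#' @param presence_probs per-circ presence probability (scalar or vector).
#' @param n_false_positive circRNAs planted into the poly-A set
#'   (<= `n_circ`).
#' @param bsj_mean,linear_mean Poisson means for BSJ and linear counts.
#' @param seed RNG seed.
#' @return list with `dataset` (a [circ_dataset()]) and `truth`.
#' @export
simulate_circ_dataset <- function(n_circ, n_samples, presence_probs = 0.5,
                                  n_false_positive = 0, bsj_mean = 4,
                                  linear_mean = 20, seed = 1L) {
  pt_assert(n_false_positive <= n_circ, "infeasible",
            "n_false_positive must be <= n_circ")
  presence_probs <- rep_len(presence_probs, n_circ)
  pt_assert(all(presence_probs >= 0 & presence_probs <= 1), "bad_probability",
            "presence probabilities must be in [0, 1]")
  set.seed(seed)
  starts <- sort(sample.int(5e7, n_circ)) + 1000L
  ends <- starts + sample(200:2000, n_circ, replace = TRUE)
  ids <- sprintf("chr1:%d-%d", starts, ends)
  present <- matrix(stats::runif(n_circ * n_samples) < presence_probs,
                    n_circ, n_samples)
  counts <- matrix(0L, n_circ, n_samples,
                   dimnames = list(ids, sprintf("s%03d", seq_len(n_samples))))
  counts[present] <- rztpois(sum(present), bsj_mean)
  linear <- matrix(stats::rpois(n_circ * n_samples, linear_mean),
                   n_circ, n_samples, dimnames = dimnames(counts))
  host <- sprintf("GENE%03d", sample.int(max(3L, ceiling(n_circ / 3)),
                                         n_circ, replace = TRUE))
  fp <- ids[seq_len(n_false_positive)]
  list(dataset = circ_dataset(counts, host_gene_start = host,
                              host_gene_end = host, polya_ids = fp,
                              linear_counts = linear),
       truth = truth_record("circ_dataset", seed,
                            presence_probs = stats::setNames(presence_probs, ids),
                            false_positive_ids = fp, host = stats::setNames(host, ids)))
}

#' Simulate a case-cohort biomarker table
#'
#' Log10 concentration is a planted linear predictor in gestational age (GA,
#' weeks), maternal weight (WT, kg) and sample storage time (SST, years) plus
#' Gaussian noise; cases are shifted upward by `case_shift` on the log10
#' scale. The design mirrors a random sub-cohort plus two case groups
#' measured at ~36 weeks.
#'
#' @param n_subcohort random sub-cohort size (>= 30).
#' @param n_cases_a,n_cases_b case-group sizes (e.g. PE and FGR).
#' @param coefficients numeric (intercept, b_GA, c_WT, d_SST) on the log10
#'   concentration scale.
#' @param noise_sigma residual SD on the log10 scale (>= 0).
#' @param case_shift upward log10 shift applied to cases.
#' @param seed RNG seed.
#' @return list with `table` (data.frame subject_id, concentration, GA, WT,
#'   SST, subcohort, group) and `truth`.
#' @export
simulate_biomarker_cohort <- function(n_subcohort = 289, n_cases_a = 116,
                                      n_cases_b = 100,
                                      coefficients = c(1.2, 0.03, -0.002, -0.005),
                                      noise_sigma = 0.15, case_shift = 0.25,
                                      seed = 1L) {
  pt_assert(n_subcohort >= 30, "bad_n", "n_subcohort must be >= 30")
  pt_assert(noise_sigma >= 0, "bad_sigma", "noise_sigma must be >= 0")
  pt_assert(length(coefficients) == 4, "bad_coefficients",
            "coefficients = (intercept, b_GA, c_WT, d_SST)")
  set.seed(seed)
  n <- n_subcohort + n_cases_a + n_cases_b
  GA <- stats::rnorm(n, 36, 0.5)
  WT <- pmax(40, stats::rnorm(n, 72, 13))
  SST <- pmax(0.1, stats::rnorm(n, 5, 1.5))
  group <- c(rep("CTL", n_subcohort), rep("PE", n_cases_a), rep("FGR", n_cases_b))
  shift <- ifelse(group == "CTL", 0, case_shift)
  log10_conc <- coefficients[1] + coefficients[2] * GA + coefficients[3] * WT +
    coefficients[4] * SST + shift + stats::rnorm(n, 0, noise_sigma)
  tab <- data.frame(subject_id = sprintf("subj%04d", seq_len(n)),
                    concentration = 10^log10_conc,
                    GA = GA, WT = WT, SST = SST,
                    subcohort = group == "CTL", group = group,
                    stringsAsFactors = FALSE)
  list(table = tab,
       truth = truth_record("biomarker_cohort", seed,
                            coefficients = coefficients,
                            noise_sigma = noise_sigma, case_shift = case_shift))
}

#' Plant exact miRNA seed sites into a random sequence
#'
#' Returns a sequence of the requested length holding exactly `n_sites`
#' non-overlapping copies of the motif at recorded positions; background
#' windows matching the motif (including across the circular junction) are
#' re-randomized so planted counts are exact ground truth.
#'
#' @param seq_length sequence length in nt.
#' @param site_motif motif over A/C/G/T to plant (the seed-site sequence).
#' @param n_sites number of copies (`n_sites * nchar(motif) <= seq_length`).
#' @param seed RNG seed.
#' @return list with `sequence` (character), `positions` (1-based starts) and
#'   `truth`.
#' @export
plant_seed_sites <- function(seq_length, site_motif, n_sites, seed = 1L) {
  m <- nchar(site_motif)
  pt_assert(grepl("^[ACGT]+$", site_motif), "bad_motif",
            "motif must be over A/C/G/T")
  pt_assert(n_sites * m <= seq_length, "infeasible",
            "cannot pack %d sites of %d nt into %d nt", n_sites, m, seq_length)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, seq_length, replace = TRUE)
  positions <- integer(0)
  if (n_sites > 0) {
    # one site per equal-width block, at a random in-block offset
    block <- seq_length %/% n_sites
    offsets <- vapply(seq_len(n_sites), function(i)
      sample.int(block - m + 1L, 1L), integer(1))
    positions <- (seq_len(n_sites) - 1L) * block + offsets
    for (p in positions)
      seq_chars[p:(p + m - 1L)] <- strsplit(site_motif, "")[[1L]]
  }
  # scrub spurious motif copies (ring scan) not at planted positions
  repeat {
    s <- paste(seq_chars, collapse = "")
    ring <- paste0(s, substr(s, 1L, m - 1L))
    hits <- Biostrings::start(Biostrings::matchPattern(site_motif,
                                                       Biostrings::DNAString(ring)))
    hits <- hits[hits <= seq_length]
    spurious <- setdiff(hits, positions)
    if (!length(spurious)) break
    for (p in spurious) {
      idx <- ((p - 1L + seq_len(m) - 1L) %% seq_length) + 1L
      idx <- setdiff(idx, unlist(lapply(positions, function(q) q:(q + m - 1L))))
      if (length(idx)) seq_chars[idx[1L]] <- sample(setdiff(bases, seq_chars[idx[1L]]), 1L)
    }
  }
  list(sequence = paste(seq_chars, collapse = ""), positions = positions,
       truth = truth_record("seed_sites", seed, motif = site_motif,
                            n_sites = n_sites, positions = positions))
}
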