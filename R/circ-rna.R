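# circRNA post-detection filtering, junction-ratio statistics, host-gene
# census, and miRNA seed-match sponge screening.

#' circRNA dataset container
#'
#' Back-splice-junction (BSJ) records: IDs of the form `"chrom:start-end"`
#' (1-based inclusive acceptor/donor positions), per-sample BSJ counts,
#' optional host-gene assignments at each end, and a companion set of IDs
#' detected in a poly-A selected (oligo-dT) negative-control library.
#'
#' @param counts nonnegative matrix of BSJ read counts, circRNAs x samples;
#'   rownames are circ IDs.
#' @param host_gene_start,host_gene_end optional host-gene IDs at the two BSJ
#'   ends (`NA` = unknown).
#' @param polya_ids circ IDs also seen in the poly-A control library.
#' @param linear_counts optional matched linear-junction counts.
#' @return a list of class `circ_dataset`.
#' @export
circ_dataset <- function(counts, host_gene_start = NULL, host_gene_end = NULL,
                         polya_ids = character(0), linear_counts = NULL) {
  counts <- as.matrix(counts)
  ids <- rownames(counts)
  pt_assert(!is.null(ids), "missing_ids", "circ IDs (rownames) required")
  pt_assert(!anyDuplicated(ids), "duplicate_id", "duplicate circ IDs")
  pt_assert(all(counts >= 0), "negative_value", "BSJ counts must be >= 0")
  n <- nrow(counts)
  if (is.null(host_gene_start)) host_gene_start <- rep(NA_character_, n)
  if (is.null(host_gene_end)) host_gene_end <- rep(NA_character_, n)
  structure(list(counts = counts,
                 host_gene_start = as.character(rep_len(host_gene_start, n)),
                 host_gene_end = as.character(rep_len(host_gene_end, n)),
                 polya_ids = as.character(polya_ids),
                 linear_counts = linear_counts),
            class = "circ_dataset")
}

#' Filter circRNA candidates
#'
#' Retains a candidate iff (1) it is present (BSJ count > 0) in at least
#' `presence_min_count(n_samples, min_presence_frac)` samples, (2) it is not a
#' read-through product (both BSJ ends assigned to the same host gene), and
#' (3) its ID is absent from the poly-A negative-control set (back-spliced
#' RNAs lack a poly-A tail, so detection in an oligo-dT library marks a likely
#' false positive). Candidates without a host-gene map are conservatively
#' retained and flagged.
#'
#' @param dataset a [circ_dataset()].
#' @param polya_ids override for the companion poly-A ID set.
#' @param min_presence_frac cohort presence fraction (default 0.3, at-least).
#' @param drop_read_through drop candidates whose two ends map to different
#'   genes (default `TRUE`).
#' @return list with `retained` (circ IDs), `kept` (logical per input),
#'   `flag_no_host` (retained but host unknown), and `reasons` per dropped ID.
#' @export
filter_circ_candidates <- function(dataset, polya_ids = NULL,
                                   min_presence_frac = 0.3,
                                   drop_read_through = TRUE) {
  stopifnot(inherits(dataset, "circ_dataset"))
  if (is.null(polya_ids)) polya_ids <- dataset$polya_ids
  ids <- rownames(dataset$counts)
  n_samp <- ncol(dataset$counts)
  need <- presence_min_count(n_samp, min_presence_frac, strict = FALSE)
  present <- rowSums(dataset$counts > 0) >= need
  host_known <- !is.na(dataset$host_gene_start) & !is.na(dataset$host_gene_end)
  read_through <- host_known &
    dataset$host_gene_start != dataset$host_gene_end
  in_polya <- ids %in% polya_ids
  kept <- present & !in_polya & !(drop_read_through & read_through)
  reasons <- character(0)
  if (any(!kept)) {
    r <- ifelse(!present[!kept], "below_presence",
                ifelse(in_polya[!kept], "polyA_control", "read_through"))
    reasons <- stats::setNames(r, ids[!kept])
  }
  list(retained = ids[kept], kept = kept,
       flag_no_host = ids[kept & !host_known], reasons = reasons)
}

#' Back-splice junction ratio
#'
#' `"ciri"`: `2*bsj / (2*bsj + linear)` — each circular molecule contributes
#' two junction-spanning read classes; `"simple"`: `bsj / (bsj + linear)`.
#'
#' @param bsj,linear nonnegative counts (vectorized); `bsj + linear > 0`.
#' @param formula `"ciri"` (default) or `"simple"`.
#' @return list with `ratio` in \[0, 1\] and the `formula` used.
#' @export
circ_junction_ratio <- function(bsj, linear, formula = c("ciri", "simple")) {
  formula <- match.arg(formula)
  pt_assert(all(bsj >= 0) && all(linear >= 0), "negative_value", "counts must be >= 0")
  pt_assert(all(bsj + linear > 0), "zero_total", "bsj + linear must be > 0")
  ratio <- if (formula == "ciri") 2 * bsj / (2 * bsj + linear)
           else bsj / (bsj + linear)
  list(ratio = ratio, formula = formula)
}

#' Census of genes hosting multiple circRNAs
#'
#' @param host_genes character vector: host gene per retained circRNA
#'   (`NA` ignored).
#' @param min_circ_per_gene census threshold (default 10).
#' @return data.frame (`gene`, `n_circ`) of genes at/above the threshold,
#'   sorted by count descending then gene ID; attribute `"all_counts"` holds
#'   the full per-gene table.
#' @export
host_gene_circ_census <- function(host_genes, min_circ_per_gene = 10) {
  host_genes <- host_genes[!is.na(host_genes)]
  if (!length(host_genes)) {
    out <- data.frame(gene = character(0), n_circ = integer(0))
    attr(out, "all_counts") <- out
    return(out)
  }
  tab <- table(host_genes)
  all_counts <- data.frame(gene = names(tab), n_circ = as.integer(tab),
                           stringsAsFactors = FALSE)
  all_counts <- all_counts[order(-all_counts$n_circ, all_counts$gene), , drop = FALSE]
  rownames(all_counts) <- NULL
  out <- all_counts[all_counts$n_circ >= min_circ_per_gene, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_counts") <- all_counts
  out
}

#' Seed definition for miRNA target matching
#'
#' The default seed is miRNA positions 2-8 (a 7mer); a site is a perfect
#' reverse-complement of the seed in the target.
#'
#' @param from,to 1-based positions on the miRNA (span >= 6 nt).
#' @return list of class `seed_definition`.
#' @export
seed_definition <- function(from = 2L, to = 8L) {
  pt_assert(to - from + 1L >= 6L, "bad_seed", "seed span must be >= 6 nt")
  structure(list(from = as.integer(from), to = as.integer(to)),
            class = "seed_definition")
}

#' Sponge-hit record with per-kb seed density
#'
#' Density arithmetic: `density = n_sites / (length_nt / 1000)`, reported raw
#' and floored to an integer (the convention for printed per-kb densities).
#'
#' @param circ_id,mirna_id identifiers.
#' @param n_sites number of seed matches.
#' @param length_nt circRNA length in nt.
#' @param positions optional 1-based site start positions.
#' @return list of class `sponge_hit`.
#' @export
sponge_hit <- function(circ_id, mirna_id, n_sites, length_nt, positions = NULL) {
  if (!is.null(positions))
    pt_assert(length(positions) == n_sites, "bad_sites",
              "n_sites must equal the number of positions")
  density <- n_sites / (length_nt / 1000)
  structure(list(circ_id = circ_id, mirna_id = mirna_id,
                 n_sites = as.integer(n_sites), length_nt = as.integer(length_nt),
                 density = density, density_int = as.integer(floor(density + 1e-9)),
                 positions = positions),
            class = "sponge_hit")
}

#' Count miRNA seed matches on a circRNA sequence
#'
#' Counts (possibly overlapping) occurrences of the reverse complement of the
#' miRNA seed span in the circRNA sequence. By default the sequence is
#' treated as a ring: windows crossing the back-splice junction are included
#' (scanning the doubled sequence, keeping matches starting in the first
#' copy). `circular = FALSE` gives a plain linear scan.
#'
#' @param circ_seq circRNA sequence (character, A/C/G/T/U).
#' @param mirna_seq miRNA sequence (character, A/C/G/U/T).
#' @param seed a [seed_definition()].
#' @param circular include junction-crossing windows (default `TRUE`).
#' @param circ_id,mirna_id identifiers carried into the result.
#' @return a [sponge_hit()].
#' @export
count_seed_matches <- function(circ_seq, mirna_seq, seed = seed_definition(),
                               circular = TRUE, circ_id = "circ",
                               mirna_id = "mirna") {
  circ_seq <- toupper(gsub("U", "T", toupper(circ_seq)))
  mirna_seq <- toupper(gsub("U", "T", toupper(mirna_seq)))
  pt_assert(seed$to <= nchar(mirna_seq), "bad_seed",
            "seed span exceeds miRNA length")
  L <- nchar(circ_seq)
  seed_seq <- substr(mirna_seq, seed$from, seed$to)
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed_seq)))
  m <- nchar(site)
  pt_assert(L >= m, "bad_seed", "circRNA shorter than the seed site")
  subject <- if (circular) paste0(circ_seq, substr(circ_seq, 1L, m - 1L)) else circ_seq
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(subject))
  starts <- Biostrings::start(hits)
  starts <- starts[starts <= L]  # distinct ring starts only
  sponge_hit(circ_id, mirna_id, length(starts), L, positions = starts)
}

#' Rank circRNA sponge candidates by seed-site load
#'
#' Computes seed matches for every circRNA x miRNA pair, keeps hits with raw
#' per-kb density strictly above `min_density_per_kb`, and ranks by site
#' count descending (ties: density, then circ ID).
#'
#' @param circ_seqs named character vector of circRNA sequences.
#' @param mirna_seqs named character vector of miRNA sequences.
#' @param seed a [seed_definition()].
#' @param min_density_per_kb density threshold (default 10).
#' @param circular ring-scan flag passed to [count_seed_matches()].
#' @return data.frame (`circ_id`, `mirna_id`, `n_sites`, `length_nt`,
#'   `density`, `density_int`), ranked.
#' @export
rank_sponge_candidates <- function(circ_seqs, mirna_seqs,
                                   seed = seed_definition(),
                                   min_density_per_kb = 10, circular = TRUE) {
  rows <- list()
  for (ci in names(circ_seqs)) for (mi in names(mirna_seqs)) {
    h <- count_seed_matches(circ_seqs[[ci]], mirna_seqs[[mi]], seed,
                            circular = circular, circ_id = ci, mirna_id = mi)
    if (h$density > min_density_per_kb)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = ci, mirna_id = mi, n_sites = h$n_sites,
        length_nt = h$length_nt, density = h$density,
        density_int = h$density_int, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(circ_id = character(0), mirna_id = character(0),
                      n_sites = integer(0), length_nt = integer(0),
                      density = numeric(0), density_int = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_sites, -out$density, out$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy false-discovery rate
#'
#' `FDR = n_decoy / n_target`, the standard estimate from a search against a
#' reversed-sequence decoy database.
#'
#' @param n_target number of target hits (> 0).
#' @param n_decoy number of decoy hits (>= 0).
#' @return the FDR estimate.
#' @export
target_decoy_fdr <- function(n_target, n_decoy) {
  pt_assert(n_target > 0, "bad_n", "n_target must be > 0")
  pt_assert(n_decoy >= 0, "bad_n", "n_decoy must be >= 0")
  n_decoy / n_target
}
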