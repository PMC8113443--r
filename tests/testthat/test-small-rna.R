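make_catalog <- function() {
  annotation_catalog(
    mature_mirna = interval_set("chr1", c(1000, 5000), c(1022, 5022),
                                id = c("mir1", "mir2"), strand = c("+", "-")),
    precursor_mirna = interval_set("chr1", 980, 1080, id = "pre1", strand = "+"),
    pirna = interval_set("chr1", c(2000, 2500), c(2030, 2528),
                         id = c("pi1", "pi2"), strand = c("+", "+")),
    trna = interval_set("chr1", 3000, 3072, id = "trna1", strand = "+"),
    sncrna = interval_set("chr1", 4000, 4100, id = "sno1", strand = "+"),
    exon = interval_set("chr1", 6000, 6500, id = "ex1", strand = "+"))
}

test_that("overlap quantification enforces the 30%-of-locus rule and strandedness", {
  loci <- interval_set("chr1", 0, 100, id = "L", strand = "+")
  # overlap 29 vs 30 of a 100 bp locus
  r29 <- interval_set("chr1", 71, 129, id = "r", strand = "+", multiplicity = 5L)
  r30 <- interval_set("chr1", 70, 129, id = "r", strand = "+", multiplicity = 5L)
  expect_equal(quantify_by_overlap(r29, loci)$count, 0)
  expect_equal(quantify_by_overlap(r30, loci)$count, 5)
  # read fully containing the locus
  big <- interval_set("chr1", -10 + 10, 200, id = "r", strand = "+", multiplicity = 2L)
  expect_equal(quantify_by_overlap(big, loci)$count, 2)
  # opposite strand never counts
  anti <- interval_set("chr1", 0, 100, id = "r", strand = "-", multiplicity = 9L)
  expect_equal(quantify_by_overlap(anti, loci)$count, 0)
  expect_error(quantify_by_overlap(r30, loci, min_frac_of_locus = 0),
               class = "placentatools_bad_fraction")
})

test_that("overlap quantification equals the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n_r <- 200; n_l <- 40
    reads <- interval_set("chr1", st <- sample.int(5000, n_r),
                          st + sample(18:35, n_r, replace = TRUE),
                          strand = sample(c("+", "-"), n_r, TRUE),
                          multiplicity = sample.int(20, n_r, TRUE))
    loci <- interval_set("chr1", ls <- sample.int(5000, n_l),
                         ls + sample(20:120, n_l, replace = TRUE),
                         id = paste0("L", 1:n_l),
                         strand = sample(c("+", "-"), n_l, TRUE))
    got <- quantify_by_overlap(reads, loci)
    expect_equal(setNames(got$count, got$id), oracle_quantify(reads, loci))
  }
})

test_that("cascades assign reads to the first claiming class and conserve multiplicity", {
  catalog <- make_catalog()
  # 5-read fixture spanning the cascade branches (hand-traced)
  reads <- interval_set("chr1",
                        c(1021, 2000, 2510, 3010, 9000),
                        c(1049, 2028, 2538, 3038, 9028),
                        id = paste0("r", 1:5), strand = "+",
                        multiplicity = c(4L, 7L, 2L, 3L, 11L))
  res <- classify_reads(reads, catalog, cascade_pirna())
  # r1 overlaps mir1 by 1 bp -> excluded at the miRNA stage
  expect_identical(res$assignment,
                   c("mature_mirna", "pirna", "pirna", "unassigned", "unassigned"))
  expect_equal(sum(res$class_multiplicity), sum(reads$multiplicity))
  res2 <- classify_reads(reads, catalog, cascade_sncrna())
  expect_identical(res2$assignment[4], "trna")
  expect_equal(sum(res2$class_multiplicity), sum(reads$multiplicity))
  # exclusion is idempotent: reclassifying the unassigned changes nothing
  left <- reads[res2$assignment == "unassigned", , drop = FALSE]
  res3 <- classify_reads(left, catalog, cascade_sncrna())
  expect_true(all(res3$assignment == "unassigned"))
  expect_error(classify_reads(reads, catalog,
                              list(list(class = "nonsense", rule = "any"))),
               class = "placentatools_unknown_class")
})

test_that("closed-world synthetic reads are fully claimed by annotated classes", {
  catalog <- make_catalog()
  sim <- simulate_small_rna_reads(catalog, reads_per_locus = 4, seed = 31)
  full_cascade <- list(list(class = "mature_mirna", rule = "any"),
                       list(class = "precursor_mirna", rule = "any"),
                       list(class = "pirna", rule = "any"),
                       list(class = "trna", rule = "any"),
                       list(class = "sncrna", rule = "any"),
                       list(class = "exon", rule = "any"))
  res <- classify_reads(sim$reads, catalog, full_cascade)
  expect_false("unassigned" %in% res$assignment)
  expect_equal(sum(res$class_multiplicity), sum(sim$reads$multiplicity))
})

test_that("reciprocal consensus filter requires 30% of both lengths on the same strand", {
  cand <- interval_set("chr1", c(0, 1000, 2000), c(100, 1100, 2100),
                       id = c("c1", "c2", "c3"), strand = "+")
  # c1: support overlapping 30 bp of both (100 bp each) -> kept
  # c2: no support; c3: support 1000 bp, overlap 100 (10% of support) -> dropped
  sup <- interval_set("chr1", c(70, 2000), c(170, 3000),
                      id = c("s1", "s2"), strand = "+")
  kept <- consensus_novel_mirna(cand, list(sup))
  expect_identical(kept$id, "c1")
  # 29 bp reciprocal overlap fails
  sup29 <- interval_set("chr1", 71, 171, id = "s", strand = "+")
  expect_equal(nrow(consensus_novel_mirna(cand[1, ], list(sup29))), 0)
  # no supports -> empty
  expect_equal(nrow(consensus_novel_mirna(cand, list())), 0)
  # support on any one of several lists suffices
  kept2 <- consensus_novel_mirna(cand, list(sup29, sup))
  expect_identical(kept2$id, "c1")
})

test_that("novel locus discovery: exclusion, multiplicity threshold, merge semantics", {
  catalog <- make_catalog()
  reads <- interval_set("chr1",
                        c(6100, 8000, 8020, 8500, 9000),
                        c(6128, 8028, 8048, 8528, 9028),
                        id = paste0("r", 1:5), strand = c("+", "+", "+", "+", "-"),
                        multiplicity = c(50L, 12L, 15L, 9L, 10L))
  loci <- discover_novel_smallrna_loci(reads, catalog, min_multiplicity = 10)
  # r1 in exon -> excluded; r4 multiplicity 9 -> dropped; r2+r3 overlap 8 bp -> merged
  expect_equal(nrow(loci), 2)
  merged <- loci[loci$strand == "+", ]
  expect_equal(c(merged$start, merged$end), c(8000, 8048))
  expect_equal(merged$multiplicity, 27L)
  expect_equal(loci$multiplicity[loci$strand == "-"], 10L)
  # same span on opposite strands never merges
  pair <- interval_set("chr1", c(100, 100), c(128, 128), id = c("a", "b"),
                       strand = c("+", "-"), multiplicity = c(10L, 10L))
  expect_equal(nrow(discover_novel_smallrna_loci(pair, catalog)), 2)
  # book-ended reads (0 bp shared) stay separate
  touch <- interval_set("chr1", c(100, 128), c(128, 156), id = c("a", "b"),
                        strand = "+", multiplicity = c(10L, 10L))
  expect_equal(nrow(discover_novel_smallrna_loci(touch, catalog)), 2)
  expect_error(discover_novel_smallrna_loci(reads, catalog, min_multiplicity = 0),
               class = "placentatools_bad_multiplicity")
})

test_that("planted novel loci are recovered exactly from synthetic reads", {
  catalog <- make_catalog()
  planted <- interval_set("chr2", c(100, 900), c(128, 926),
                          id = c("n1", "n2"), strand = c("+", "-"),
                          multiplicity = c(12L, 30L))
  sim <- simulate_small_rna_reads(catalog, reads_per_locus = 3,
                                  planted_novel = planted, seed = 41,
                                  multiplicity_mean = 3)
  # push catalog-derived reads below threshold via min_multiplicity > their max
  loci <- discover_novel_smallrna_loci(sim$reads, catalog, min_multiplicity = 12)
  on2 <- loci[order(loci$start), ]
  expect_equal(on2$start, planted$start)
  expect_equal(on2$end, planted$end)
  expect_identical(on2$strand, planted$strand)
  # planted loci overlapping the catalog are rejected at generation
  bad <- interval_set("chr1", 6100, 6130, id = "bad", strand = "+",
                      multiplicity = 10L)
  expect_error(simulate_small_rna_reads(catalog, planted_novel = bad),
               class = "placentatools_planted_overlap")
})

test_that("sample-frequency table applies thresholds and is monotone", {
  pres <- matrix(0L, 5, 10)
  pres[1, ] <- 1L              # ubiquitous
  pres[2, 1:3] <- 1L           # 30%
  pres[3, 1:2] <- 1L           # 20%
  tab <- sample_frequency_table(pres, fractions = c(0.3, 1.0))
  expect_equal(tab$n_loci, c(2, 1))
  expect_equal(tab$min_samples, c(3L, 10L))
  set.seed(8)
  rnd <- matrix(rbinom(200, 1, 0.4), 20, 10)
  tab2 <- sample_frequency_table(rnd, fractions = c(0.1, 0.3, 0.7, 1.0))
  expect_true(all(diff(tab2$n_loci) <= 0))
})

test_that("read-length distribution is multiplicity-weighted with smallest-mode ties", {
  reads <- interval_set("chr1", c(0, 100, 200), c(21, 128, 230),
                        id = c("a", "b", "c"), strand = "+",
                        multiplicity = c(3L, 10L, 2L))
  rl <- read_length_distribution(reads)
  expect_equal(rl$mode, 28)
  expect_equal(rl$histogram$weight[rl$histogram$length == 28], 10)
  tie <- interval_set("chr1", c(0, 100), c(22, 130), id = c("a", "b"),
                      strand = "+", multiplicity = c(5L, 5L))
  expect_equal(read_length_distribution(tie)$mode, 22)  # smallest on ties
  expect_error(read_length_distribution(reads[0, ]),
               class = "placentatools_empty_input")
})

test_that("synthetic read lengths peak at the requested mode", {
  catalog <- annotation_catalog(
    exon = interval_set("chr3", seq(0, 9000, by = 1000),
                        seq(0, 9000, by = 1000) + 200,
                        strand = "+"))
  sim <- simulate_small_rna_reads(catalog, reads_per_locus = 30,
                                  length_mode = 28, seed = 55)
  expect_equal(read_length_distribution(sim$reads)$mode, 28)
})
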