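# placentatools

Statistical machinery for bulk placental total-RNA and small-RNA
transcriptome studies. The placenta expresses an unusually small set of
transcripts at very high levels — a handful of genes can account for half of
all sequenced reads — and it hosts distinctive RNA populations (circular
RNAs, piRNAs, placenta-enriched mRNAs) whose analysis needs bespoke
filtering and testing rather than off-the-shelf differential expression
alone. This package implements those statistics as tested, reusable R
functions, together with seeded synthetic-data generators that plant ground
truth for every analysis, so each method can be validated end to end without
access-restricted patient data.

## What is implemented

**Transcriptome complexity** — unit conversions (counts → RPM/RPKM, RPKM →
TPM), the TA50 statistic (the number of transcripts, in descending abundance
order, needed to reach 50% of total abundance), cumulative abundance curves,
top-fraction shares, and abundance-class tables with the "undetected"
(exactly zero) class kept separate from (0, 0.1) RPKM.

**Tissue enrichment** — TMM normalization factors (via edgeR), per-tissue
TPM panels, and the Tau tissue-specificity score

&nbsp;&nbsp;&nbsp;&nbsp;Tau = Σᵢ (1 − xᵢ/max) / (n − 1),

with strict (Tau > 0.99, TPM > 1, >100× the mean of the remaining tissues,
protein-coding/lincRNA) and relaxed (Tau > 0.9, 10×) enrichment rules.

**Small-RNA classification** — strand-aware interval-overlap cascades for
collapsed reads (each read carries a multiplicity): any-overlap exclusion
against miRNA/piRNA/tRNA/exon annotations, quantification by the
≥30%-of-locus rule, reciprocal 30% consensus filtering of novel miRNA
candidates, novel-locus discovery (multiplicity ≥ 10, ≥1 bp same-strand
merging), sample-frequency tables, and multiplicity-weighted read-length
distributions.

**circRNA filtering and sponge screening** — prevalence filtering
(present in ≥30% of the cohort), subtraction of candidates detected in
poly-A selected negative-control libraries, read-through removal, back-splice
junction ratios (2·BSJ/(2·BSJ + linear) or the simple ratio), host-gene
censuses, perfect-seed-match counting on circular sequences (ring scan
across the back-splice junction), per-kb sponge-site densities, and the
target-decoy FDR formula.

**Bootstrap fold-change concordance** — the package's core test. Matched
case-control pairs are resampled with replacement (n pairs per replicate);
the replicate fold change of transcript i is the ratio of resampled case and
control means,

&nbsp;&nbsp;&nbsp;&nbsp;FCᵢᵏ = mean RPMᵢᵏ(cases) / mean RPMᵢᵏ(controls),
&nbsp;&nbsp;&nbsp;&nbsp;FCᵢ = (Σₖ FCᵢᵏ) / n_boot.

Within the most abundant transcripts, the top |log₂ FC| fraction of each of
two phenotypes is selected with direction signs, and sharing in the same
direction is tested with a two-sided Fisher exact test on
(n_same, k − n_same; k − n_same, N − 2k + n_same) over the union background,
computed in log space so P values of order 10⁻⁶² are exact. Eligibility
filtering (RPM ≥ 0.2, present in >10% of each cohort, both cohorts, chrY/chrMT
excluded), Benjamini-Hochberg adjustment and Spearman correlation screens are
included.

**Serum biomarker analysis** — multiples of the median (MoM) against a random
sub-cohort, the log-linear covariate correction
corrected MoM = MoM / 10^(a + b·GA + c·WT + d·SST),
97th-percentile dichotomization, odds ratios with Woolf CIs, and per-group
exact tests.

**Cohort QC and matching** — decidual-contamination flagging by
fold-over-median on a seven-gene marker panel, greedy priority-ordered
case-control matching (labor, gestational age, fetal sex, caesarean,
smoking, BMI, maternal age), and rule-based pair exclusion.

## Worked example

Simulate two matched phenotypes sharing planted two-fold features, run the
bootstrap, select top-ranked transcripts and test their concordance:

```r
library(placentatools)

# 82-pair and 40-pair phenotypes over one feature space, 30 planted
# two-fold features each, half shared
sim <- simulate_paired_cohort(n_pairs_a = 82, n_pairs_b = 40, n_features = 500,
                              planted_up_a = 30, planted_up_b = 30,
                              overlap_frac = 0.5, effect_log2 = 1, seed = 1)

fc_for <- function(cohort) {
  case <- sim$matrix$values[, cohort$sample_id[cohort$role == "case"]]
  ctl  <- sim$matrix$values[, cohort$sample_id[cohort$role == "control"]]
  bootstrap_fold_changes(case, ctl, n_boot = 2000, seed = 2)
}
boot_a <- fc_for(sim$cohort_a)
boot_b <- fc_for(sim$cohort_b)

abund <- rowMeans(sim$matrix$values)
top_a <- select_top_ranked(boot_a, abund, abundance_subset_ratio = 0.5, top_frac = 0.1)
top_b <- select_top_ranked(boot_b, abund, abundance_subset_ratio = 0.5, top_frac = 0.1)
overlap_concordance_test(top_a, top_b)
#> <overlap_test> 10/25 shared same-direction (+0 opposite), N = 250, P = 1.99e-05
```

Ten of the 25 top-ranked transcripts in each phenotype are shared with the
same fold-change direction; under random selection from the 250-transcript
abundance background the expected overlap is 25·25/250 = 2.5, and the Fisher
exact P of 2×10⁻⁵ quantifies the excess — the same construction used to
compare the two disease phenotypes at full cohort scale.

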