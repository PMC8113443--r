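---
title: "Methods: statistics for placental transcriptome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics for placental transcriptome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentatools)
```

This vignette is the package's own account of the statistical methods it
implements: the models and procedures, their assumptions, the parameters
that matter, the numerical and design choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## Coordinate and unit conventions

All genomic intervals are stored 0-based half-open (the BED convention), and
all overlap arithmetic happens in that system. Text coordinates of the form
`"chr19:53,686,484-53,752,432"` are 1-based inclusive — the style used in
published genome-browser spans — and are converted exactly once, at the
boundary, by `text_coords_to_interval()`; the length of such a span is
E − S + 1. Mitochondrial names are normalized at ingestion ("MT" and
"chrMT" become "chrM").

Expression values always carry a declared unit (`count`, `RPM`, `RPKM`,
`TPM`), and operations that are only meaningful on one scale refuse others:
the eligibility filter, for instance, accepts RPM (or counts, for circRNA
tables) and raises a classed error for TPM. RPM is counts rescaled to a
per-million library; RPKM additionally divides by transcript length in kb;
TPM is RPKM rescaled so each profile sums to 10⁶ (this rescaling is
idempotent, which the tests exploit).

Presence thresholds convert a cohort fraction to a minimum sample count with
two deliberate semantics: *at least 30%* uses `ceiling(f·n)` and *more than
10%* uses `floor(f·n) + 1`. On a 295-sample cohort these give 89 and 30
respectively — both arise as worked numbers in the cohort designs this
package targets — and a guard of 10⁻⁹ absorbs floating-point noise around
exact integers.

## Transcriptome complexity

TA50 is the number of transcripts, taken in descending abundance order,
needed to reach half of the total abundance: a skew statistic. Ties in
abundance are broken by feature ID so the reported top set is deterministic;
TA50 itself is insensitive to tie order. A uniform profile of n transcripts
has TA50 = ⌈n/2⌉, and moving mass from a lower-ranked transcript to the top
one can never increase it (a property the test suite checks by random
perturbation). The operation takes a pre-filtered profile: whether weakly
detected transcripts (e.g. ≤ 0.1 RPKM) belong in the denominator is the
caller's decision, made before calling.

Abundance-class tables bin features into {undetected, (0, 0.1), [0.1, 1),
[1, 100], (100, 1000], (1000, 10⁴], > 10⁴} on the declared unit.
"Undetected" means exactly zero and is kept separate from (0, 0.1): the
distinction between *not detected* and *detected below 0.1 RPKM* is
biologically meaningful for sparse biotypes such as pseudogenes and piRNAs.
No plotting pseudo-count enters classification.

`top_fraction_share()` takes the top `max(1, round(f·n))` transcripts.
Throughout the package, "round" is round-half-away-from-zero
(`floor(x + 0.5)`), chosen so the worked top-k arithmetic is exact: a
5000-transcript subset yields exactly 250 transcripts at 5% and 150 at 3%.

## Tissue enrichment

Between-sample normalization uses trimmed-mean-of-M-values (TMM) factors.
The package delegates to edgeR's `calcNormFactors(method = "TMM")` — the
canonical implementation, with the reference column chosen by the
75th-percentile count fraction, two-sided trims of 30% on M values and 5% on
A values, and inverse asymptotic binomial variances as weights — and the
test suite verifies the returned factors against an independent,
from-scratch implementation of that recipe to 10⁻¹⁰. Factors are rescaled
to multiply to 1, so normalization never changes the grand scale.

The Tau tissue-specificity score for a gene with expression x across n ≥ 2
tissues is Σᵢ (1 − xᵢ/max) / (n − 1): 0 for uniform expression, 1 for
expression confined to one tissue, scale-invariant, and monotone under
concentration of mass into the maximum tissue. Enrichment flags apply, per
tissue: Tau > 0.99, TPM > 1, TPM > 100 × the arithmetic mean of the
*remaining* tissues, and an eligible biotype (protein-coding or lincRNA by
default). The relaxed preset (Tau > 0.9, 10×) exists for endogenous
retrovirus genes, whose placental expression is strong but less exclusive.
Under the strict thresholds a gene can be flagged in at most one tissue.
Genes known to be non-polyadenylated (notably replication-dependent
histones) distort comparisons against poly-A selected reference compendia;
they are handled as a caller-supplied exclusion list rather than a built-in
catalog.

The observed/expected over-representation ratio takes `expected` as an
explicit input: the expectation model behind any particular published ratio
is not always derivable from stated totals, so the package computes the
ratio and a 1-df chi-squared for whatever expectation the caller supplies
(one-cell, or two-cell Pearson when a grand total is given).

## Small-RNA classification

Collapsed reads carry a multiplicity — the number of identical sequenced
copies — and every operation is strand-aware. Classification is an ordered
cascade: each stage claims the reads that overlap its annotation class on
the same strand, either by ≥ 1 bp (exclusion stages) or by at least 30% *of
the annotation locus length* (quantification stages); a read goes to the
first stage that claims it, and unclaimed reads are reported as
`unassigned`, so per-class multiplicities always sum to the input total.
Two readings of the 30% rule are possible (fraction of the read vs fraction
of the locus); the package measures against the annotation locus, matching
the behavior of `intersectBed -s -f 0.3` with annotations as the
fraction-bearing operand. A read may legitimately count toward two
overlapping loci of the same class, so conservation is stated per class,
not per locus.

The preset cascades intentionally differ per target class: the piRNA
cascade excludes only mature miRNAs; the sncRNA cascade also excludes
precursor miRNAs, piRNAs and tRNAs; the novel-locus cascade additionally
excludes annotated novel miRNAs and exons. Unifying them would be tidier
but would not reproduce the established pipelines these mirror.

Novel-locus discovery removes reads overlapping any exclusion class,
removes reads with multiplicity below 10 — the threshold is collapsed-read
multiplicity, not positional pileup depth — and merges survivors
transitively when they overlap by ≥ 1 bp on the same strand. Book-ended
reads (sharing a boundary but 0 bp) are not merged; the implementation uses
`GenomicRanges::reduce(min.gapwidth = 0)` for exactly this reason.

The reciprocal consensus filter for novel miRNA candidates keeps a
candidate only if some interval in *any* support set overlaps it by ≥ 30%
of both lengths on the same strand — one confirming predictor suffices.

## circRNA filtering and sponge screening

Back-splice-junction (BSJ) candidates are retained when (1) present (BSJ
count > 0) in at least ⌈0.3·n⌉ samples, (2) not read-through products (both
junction ends in one host gene), and (3) absent from a poly-A selected
negative-control library — circular RNAs have no poly-A tail, so detection
under oligo-dT priming marks a likely false positive. When no host-gene map
is available, candidates are conservatively retained and flagged rather
than dropped.

The junction ratio defaults to 2·BSJ/(2·BSJ + linear): each circular
molecule contributes junction-spanning evidence on both sides, which is the
convention of CIRI-style detectors, and published ratios in this domain are
consistent with it. The simple BSJ/(BSJ + linear) form is available because
the verbal phrase "circular to non-circular" is genuinely ambiguous; the
formula used is recorded in the output.

Seed matching is a deliberate simplification of energy-based target
prediction: a site is a perfect reverse complement of the miRNA seed
(positions 2–8 by default, configurable), counted at every distinct start,
overlaps allowed. The sequence is treated as a ring by default — windows
crossing the back-splice junction exist on the circular molecule — with a
linear scan available since FASTA-based screens of circRNA sequences
usually do not wrap. Densities are sites per kb, reported raw and floored
to an integer (the convention in which published per-kb densities of 45 and
11 are stated); the raw density times length/1000 always equals the site
count exactly. Because thermodynamic scoring is out of scope, published
site *counts* from energy-based tools are treated as inputs to the density
arithmetic, not as quantities this package re-derives; circRNA length uses
the 1-based inclusive convention (E − S + 1), under which both printed
densities reproduce after flooring (they also do under E − S, so the choice
is not load-bearing).

## The bootstrap fold-change concordance test

This is the package's centerpiece. Conventional per-transcript P values
penalize transcripts with heterogeneous effects — a real concern when the
two phenotypes compared (preeclampsia and fetal growth restriction) are
themselves heterogeneous. The alternative implemented here:

1. **Eligibility**: a transcript qualifies if, in *each* cohort, strictly
   more than 10% of samples reach the abundance threshold (RPM ≥ 0.2;
   count ≥ 5 for circRNAs), and it is not on chrY or chrMT (sex-linked and
   mitochondrial transcripts confound case-control comparisons in
   pregnancy cohorts).
2. **Bootstrap**: matched case-control pairs are resampled with
   replacement to the original pair count; per replicate,
   FCᵢᵏ = mean(case)/mean(control); the reported FCᵢ is the arithmetic mean
   of FCᵢᵏ over replicates (10,000 by default). The resampling unit is the
   *pair* — resampling cases and controls independently would break the
   matching — though an independent variant is available behind a flag.
   Replicates in which transcript i's control mean is zero would give an
   infinite ratio; they are dropped from that transcript's mean and
   counted, which is practically unbiased because the eligibility filter
   bounds zero-prevalence. A Monte-Carlo standard error of each FCᵢ is
   reported.
3. **Top-k selection**: fold-change magnitude is unreliable for weakly
   expressed transcripts, so selection is restricted to the most abundant
   subset (ratio 5000/15257 of the eligible set by default, by mean RPM).
   Within it, transcripts are ranked by |log₂ FCᵢ| with ties broken by ID,
   and the top 5% (or 3%) are selected, each carrying sign(log₂ FCᵢ).
   Ranking by *absolute* log fold change is a considered choice: ranking
   signed values "in descending order" could never produce shared
   transcripts with opposite directions, yet opposite-direction sharing is
   a real, reportable outcome; absolute ranking with recorded signs
   reconciles the two.
4. **Sharing test**: with k transcripts selected per phenotype from a
   background of N (the union of the two abundance subsets), and n_same
   shared with equal signs, the 2×2 table
   (n_same, k − n_same; k − n_same, N − 2k + n_same) is tested two-sided by
   Fisher's exact test. The implementation sums hypergeometric point
   masses evaluated in log space with the standard relative tolerance of
   10⁻⁷ on the "as extreme" comparison, so P values of order 10⁻⁶² are
   representable and agree with `stats::fisher.test` to high precision; an
   exhaustive enumeration oracle verifies all tables with N ≤ 60. A
   500-replicate simulated null (random signed sets, N = 400, k = 20) in
   the test suite checks the test is not anticonservative.

## Serum biomarker analysis

The case-cohort design measures an analyte in all cases plus a random
sub-cohort. Concentrations become multiples of the median (MoM) of the
sub-cohort; a log-linear regression of log₁₀ MoM on gestational age
(weeks), maternal weight (kg) and sample storage time (years), fitted on
the sub-cohort only, yields the correction
corrected MoM = MoM / 10^(a + b·GA + c·WT + d·SST). The 97th-percentile
cutoff of corrected MoMs is computed in the sub-cohort by linear
interpolation of order statistics (h = (n − 1)p + 1, quantile type 7 — the
estimator is a documented choice, as published analyses rarely state
theirs), and exceedance is strict (> cutoff), matching the phrase "above
the 97th percentile". Odds ratios use (a·d)/(b·c) with Woolf (log-scale)
95% intervals, falling back to the Haldane–Anscombe 0.5 correction (and a
flag) when a cell is zero; group comparisons use the same two-sided Fisher
exact test as the concordance module. The odds-ratio *point estimates* are
the quantities this package reproduces from reconstructed tables;
published interval bounds depend on the CI method, which is documented
rather than matched.

## Cohort QC and matching

Decidual contamination of chorionic-villus samples is flagged by
fold-over-median: each of seven decidua-enriched markers (IGFBP1, OMD, PRL,
RBP4, KIAA1644, RORB, CHRDL1) is divided by its cohort median, and a sample
is flagged when at least a quorum of markers reaches 20-fold. Published
rules state the fold threshold but not the quorum; the default — a majority
of usable markers — is configurable, and markers with zero median are
skipped and reported. The rule is invariant to sample order and to uniform
rescaling.

Matching is greedy and priority-ordered: cases in input order; exact
criteria (labor, fetal sex, caesarean, smoking) enforced in priority order
and relaxed lowest-priority-first only when no candidate remains; then the
candidate minimizing the lexicographic vector of nearest-criterion
distances (gestational age before BMI before maternal age) is chosen and
removed from the pool. Ties at the end break by control ID, making the
whole procedure deterministic. This is one faithful reading of "matched as
closely as possible in order of importance", not a reconstruction of any
particular unpublished script; optimal (e.g. Hungarian) matching is
deliberately out of scope. Pair exclusion is declarative: sex mismatch,
contamination or batch flags, and disqualifying case comorbidities each
remove a pair and log which rule fired.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its parameters and seed and returns a
truth record naming exactly what was planted.

* `simulate_abundance_profile`: log-normal abundances. Log-normal (rather
  than Pareto) was chosen as the default skew model because it reproduces
  the qualitative cumulative-curve behavior of highly skewed transcriptomes
  with a single interpretable parameter; σ = 0 degenerates to uniform, and
  larger σ gives smaller TA50 (checked over 20 seeds).
* `simulate_tissue_panel`: background genes are near-uniform across tissues
  (multiplicative log-normal noise, σ = 0.2 on the log scale); planted
  enriched genes are constructed to pass the strict criteria outright
  (home-tissue TPM ≈ 50, off-tissue leakage ≤ 0.05% of home). Recovery of
  the planted set is therefore exact by construction — the test
  demonstrates the flagging logic, not detection power at marginal
  signal.
* `simulate_paired_cohort`: control values log-normal around per-feature
  baselines; cases multiplied by 2^effect on planted features; the two
  phenotypes' planted sets overlap by round(overlap_frac · min size). The
  default sizes (82 and 40 pairs) mirror the two-phenotype design the
  concordance test was built for. Note the empirical ratio of means under
  multiplicative log-normal noise carries a small upward bias (~σ²/2),
  which the tests account for.
* `simulate_small_rna_reads`: reads fall inside their source loci,
  strand-consistent, lengths peaked at 28 nt (an atom at the mode plus
  discretized Gaussian spread — 28 nt is the characteristic piRNA-range
  mode seen after miRNA exclusion); planted novel loci must be disjoint
  from the catalog and receive caller-specified multiplicities exactly.
* `simulate_circ_dataset`: per-sample presence is Bernoulli and BSJ counts
  zero-truncated Poisson conditioned on presence, matching the semantics of
  prevalence filters (presence = count > 0); planted false positives are
  emitted into the poly-A companion set.
* `simulate_biomarker_cohort`: log₁₀ concentration is a planted linear
  predictor in GA/WT/SST plus Gaussian noise, with cases shifted upward on
  the log scale; the default design (289 sub-cohort, 116 + 100 cases at
  ~36 weeks) mirrors the case-cohort geometry of the serum analysis.
* `plant_seed_sites`: exactly n non-overlapping motif copies at recorded
  positions; background windows matching the motif — including across the
  circular junction — are re-randomized until none remain, so planted
  counts are exact ground truth for the ring scan.

None of the generators model read-level sequencing error, GC or
fragment-length bias, genome-scale sequence composition, or realistic
abundance dispersion estimated from any cohort; their dispersion defaults
are chosen for test power. Passing tests therefore demonstrate that the
implementations compute their definitions correctly and recover planted
signal under the stated models — not that the methods are robust to every
artifact of real sequencing data.

## Numerical choices and degenerate inputs

* Rounding of subset sizes is half-away-from-zero throughout.
* Fisher P values are computed from log-space point masses; the "as
  extreme" comparison uses relative tolerance 10⁻⁷ (the convention of the
  standard R implementation). A zero row or column margin gives P = 1.
* Bootstrap means are accumulated as row sums divided by n, so results are
  bit-reproducible against a plain-loop re-implementation drawing the same
  RNG stream.
* All-zero profiles, zero column totals, empty inputs, rank-deficient
  design matrices, zero-length intervals, unknown cascade classes and
  unknown pipeline stages raise classed errors (`placentatools_*`), never
  silent NAs; constant vectors in correlation screens are the one
  documented exception, reported as missing values because a screen over
  thousands of features should not abort on one flat profile.
* Overlap-fraction comparisons subtract 10⁻⁹ before testing ≥, so exact
  30% boundaries are kept.

## Problem sizes in the test suite

The suite exercises full-scale bookkeeping where it is cheap (top-k
selection on 15,257 transcripts; exhaustive Fisher enumeration for all
tables with N ≤ 60) and scaled-down simulations where it is not: bootstrap
checks run 200 replicates against the bit-identical oracle and 2,000 for
planted-effect recovery on 82-pair cohorts of 200–300 features; null
calibration uses 500 replicates at N = 400, k = 20; parameter-recovery
loops use 20 seeds. These sizes were chosen to give the checks real
statistical teeth while keeping the default suite fast enough to run on
every change.

## Known limitations

* The sharing test conditions on equal top-set sizes k in both phenotypes,
  the design it was built for; unequal sizes would need generalized
  margins.
* Seed matching ignores binding energetics, wobble pairing and
  conservation; it reproduces density arithmetic exactly but is not a
  target predictor.
* DESeq2-style per-transcript inference, WGCNA modules, alignment and
  assembly are out of scope by design; the package consumes their outputs
  (count tables, annotations) rather than re-implementing them.
* The greedy matcher is order-dependent by specification (cases processed
  in input order); a `--sort-cases-by` style pre-sort is the caller's
  responsibility.
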