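Package: placentatools
Title: Statistical Toolkit for Placental Total and Small-RNA Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for bulk placental transcriptome studies:
    transcriptome-complexity summaries (TA50, cumulative abundance curves,
    abundance classes), TMM-normalized tissue-enrichment scoring with the Tau
    specificity index, interval-overlap classification of collapsed small-RNA
    reads (miRNA/piRNA/sncRNA cascades, novel-locus discovery), circRNA
    prevalence filtering with poly-A negative-control subtraction and
    miRNA-seed sponge screening, a bootstrap fold-change concordance test
    between two disease phenotypes with a direction-aware Fisher sharing test,
    serum-biomarker multiples-of-the-median correction with dichotomized odds
    ratios, and sample-level QC with priority-ordered case-control matching.
    Includes seeded synthetic-data generators with planted ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    edgeR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
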