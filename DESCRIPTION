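Package: tramseq
Title: Transcriptome-Wide RNA Accessibility Mapping Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis engine for transcriptome-wide DMS mutational
    profiling (mutational-profile RNA accessibility mapping). Converts per-base
    base-call count tables into coverage-filtered, control-corrected A/C
    reactivity profiles; segments transcripts into fixed-count A/C windows and
    scores them with Gini indices and replicate Pearson correlations to call
    structured transcripts and elements; quantifies differential accessibility
    between conditions with a per-window delta statistic and a
    within-versus-between replicate correlation t-test with Benjamini-Hochberg
    correction; normalizes reactivities into SHAPE-style folding constraints,
    folds with a reactivity-penalized base-pair maximization dynamic program
    (with an external-folder adapter), and scores structure/data agreement by
    AUROC; tests RNA-binding-protein CLIP-site enrichment among remodeled
    windows against a scrambled-location null; and ships a fully seeded
    synthetic-data generator so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
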