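Package: protspec
Title: Protease Specificity Profiling, Cleavage Entropy and Substrate
    Prediction from High-Throughput Degradomics Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives protease cleavage-site specificity fingerprints from
    peptide identification tables produced by unspecific database searches.
    Peptide termini are converted into P8-P8' cleavage windows, positional
    amino-acid frequency matrices are compared against a sampled random
    (null) distribution from the protein database to give log2 fold-change
    enrichments with paired-t significance, and per-subsite normalized
    Shannon cleavage entropy plus block-entropy cooperativity summarize
    specificity. Conditions are compared through differential enrichment,
    entropy deltas, peptide-count activity changes and Pearson hierarchical
    clustering. A motif score (sum of significant positional enrichments
    over P4-P4') scans whole proteomes for candidate substrate sites, with
    ROC-based false-positive-rate thresholding, solvent-accessibility
    filtering, and inverse-rank-product protein prioritization. A companion
    module designs best-match reporter substrates and verifies them by
    monoisotopic m/z. A PWM-driven in-silico digestion simulator provides
    ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
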