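Package: tauselect
Title: Multi-Tissue Transcriptome Profiling, Tissue-Specificity Tau, and
    Branch-Site Positive-Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a multi-tissue transcriptome and scanning
    it for lineage-specific positive selection. Quantifies expression as
    transcripts per million (TPM), calls tissue presence/absence and exclusive
    tissue intersections (UpSet-style), computes the tissue-specificity index
    tau with housekeeping-based calibration, confidence-filters transcript
    annotations from BLAST tabular hits, clusters orthologs with the Markov
    cluster algorithm, and performs the branch-site dN/dS likelihood-ratio
    test for positive selection on a tagged foreground branch using a
    Goldman-Yang codon substitution model. Includes seeded synthetic-data
    generators (expression matrices with known specificity classes, BLAST-like
    hit tables, codon alignments evolved under branch-site site-class models),
    GO overrepresentation with false-discovery-rate control, bootstrap group
    comparison, and a steroidogenic-pathway expression panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
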