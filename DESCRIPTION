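Package: hibernaseq
Title: Transcription and Steady-State RNA Dynamics Across the Torpor-Arousal Cycle
Version: 0.1.0
Authors@R: person("Liver", "Transcriptomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing hibernator liver transcriptomes
    across physiological states: transcription-unit segmentation from nascent
    (run-on) coverage and quantification of 3' readthrough past annotated
    termination sites; reference-pattern co-expression clustering; negative
    binomial differential expression with a sex covariate; concordance of
    transcriptional and steady-state fold changes with AU-rich-element k-mer
    enrichment; A-to-I editing-site detection with a cross-assay polymorphism
    filter; and a simplified percent-spliced-in (PSI) splicing classifier.
    Includes a synthetic-data generator with a written truth table so every
    stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
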