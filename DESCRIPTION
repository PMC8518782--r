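Package: markerscan
Title: Profile-HMM Screening of Marker-Gene Transcripts in
    (Meta)transcriptomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects, calibrates, screens and quantifies transcripts of
    energy-metabolism and reactive-oxygen-species (ROS) neutralization
    marker genes in assembled (meta)transcriptomes. Provides a
    self-contained profile hidden Markov model engine (HMMER3 ASCII
    reading/writing, profile construction from seed alignments, local
    Viterbi bit-score scoring), six-frame ORF prediction with the
    bacterial/archaeal genetic code, bit-score cutoff calibration from
    labeled homolog sets with competitive decoy screening, per-sample
    lineage-by-gene variant inventories with category summaries, and a
    deterministic synthetic metatranscriptome generator with a
    machine-readable truth table for offline benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
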