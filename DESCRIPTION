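Package: turnomix
Title: Multiomic Quantification of mRNA Turnover, Translation and Metabolism
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of metabolic-labelling RNA-seq, ribosome
    profiling, CLIP and mass-spectrometry data. Estimates per-gene mRNA
    half-lives from 4-thiouridine three-fraction experiments (total,
    newly-synthesised, pre-existing RNA), computes expression-local
    standard-deviation z statistics for differential comparisons, clusters
    derepressed genes into regulatory modes across transcription, stability
    and translation, calls 3'UTR targets from crosslink-site tables under
    iCLIP and HITS-CLIP consistency rules with AU-rich-element motif
    scanning, quantifies enrichment against expression- and
    3'UTR-length-matched resampled control gene sets, and corrects GC-MS
    isotopologue spectra for natural isotope abundance to obtain mass
    isotopomer distributions and fractional labelling. A synthetic-data
    generator with known ground truth emulates every input so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    pracma
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
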