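Package: cofactorscreen
Title: Detection of Cell-Type- and TF-Specific Cofactor Motifs in ChIP-seq Peak Compendia
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens compendia of transcription factor (TF) ChIP-seq peak sets
    for binding-site motifs of transcriptional cofactors that co-occur with the
    ChIP-targeted TF's canonical motif in a cell-type-specific or TF-specific
    way.  Provides curation of experiment compendia (removal of general
    transcription machinery, orphan experiments and high-occupancy-target (HOT)
    regions), position-weight-matrix parsing for JASPAR and UniPROBE dialects,
    log-odds scanning with exact p-values from the score distribution,
    proximal/distal co-occurrence abundance statistics, ubiquity and
    specificity screens, empirical motif-similarity false-positive removal,
    and a seeded synthetic-compendium generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
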