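Package: raceltr
Title: Genome-Wide RACE-Seq Analysis of LTR Retrotransposon Promoter Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing targeted 5' RACE-Seq screens of
    THE1/MST-family (MaLR) long terminal repeat activation: primer-compatibility
    scanning of repeat instances under a mismatch budget, deterministic peak
    calling with replicate-consensus filtering, RepeatMasker-style repeat and
    genomic-region annotation, Dice-index sample similarity clustering,
    hypergeometric enrichment of LTR-linked upregulated genes, strand-oriented
    metagene profiles around active LTRs, and a four-way classification of
    LTR-initiated transcripts. A synthetic-data generator plants diverged LTR
    copies, group-structured activation states, replicate capture dropout and
    LTR-driven downstream transcription, so the whole analysis runs without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
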