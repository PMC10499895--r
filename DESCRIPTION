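Package: fusionbreak
Title: Breakpoint Cluster Analysis and In Silico Assay Design for
    t(1;19) TCF3::PBX1 Translocations
Version: 0.9.0
Authors@R:
    person("fusionbreak", "authors", email = "moldx@example.org", role = c("aut", "cre"))
Description: Tools for the molecular analysis of t(1;19)(q23;p13)
    chromosomal breakpoints generating the TCF3::PBX1 fusion gene in
    B-precursor acute lymphoblastic leukemia. Provides a curated
    breakpoint catalog with intron-relative to genomic coordinate
    conversion, sliding-window and fixed-region breakpoint cluster
    statistics, classification of break sites against annotation tracks
    (DNA repeats, cryptic recombination signal sequences), a
    deterministic in silico long range-inverse PCR simulator
    (restriction digest, fragment circularization, inverse and multiplex
    product prediction, per-enzyme breakpoint detectability), fusion
    junction characterization (microhomology, non-template insertions,
    inversions, foreign inserts), breakpoint-specific qPCR design and
    standard-curve quantification for measurable residual disease, and a
    seeded synthetic derivative-chromosome generator for end-to-end
    round-trip testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
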