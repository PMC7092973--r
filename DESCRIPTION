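Package: plastomeConcord
Title: Concordance Analysis of Plastome Assemblies with Quadripartite
    Structure Modelling and Error Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing chloroplast genome (plastome) assemblies
    at the basepair level. Models the quadripartite LSC/IRb/SSC/IRa
    structure (inverted-repeat detection, IR_A stripping, SSC orientation
    normalization), aligns consensus sequences with an anchored global
    aligner, classifies alignment differences into a mismatch taxonomy
    (substitutions, deleted/inserted bases and their maximal-run events)
    with an alignment-length-referenced identity percentage, attributes
    indel error events to homopolymer context, and scans variant tables in
    fixed windows to locate high-variability marker regions and hotspots.
    A companion simulator generates quadripartite genomes, diverged
    relatives, Nanopore-style deletion-dominated corrupt consensuses,
    long-range-PCR amplicon panels, and read sets with palindromic
    chimeras, all with exact ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'alignment.R'
    'classify.R'
    'error-context.R'
    'marker-scan.R'
    'plastome-model.R'
    'plastomeConcord-package.R'
    'reports.R'
    'synthetic-data.R'
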