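Package: centroscape
Title: Centromere Landscape Analysis from CENH3 ChIP Repeat Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize plant centromeric landscapes from CENH3
    ChIP experiments and genome assemblies: alignment-free ChIP/input
    repeat-enrichment scoring against a repeat consensus library,
    summit-anchored extraction of fixed-width centromeric domains and
    chromosome morphology calls, satellite monomer-length estimation and
    windowed pairwise-identity heatmaps, de novo structural annotation of
    intact LTR retrotransposons (target-site duplications, primer binding
    sites, protein domain content, autonomy classification) with insertion
    dating from LTR divergence, and repeat-composition typing of centromeric
    domains. A synthetic-genome module generates chromosomes with planted
    satellite arrays, retroelements and ChIP/input read sets so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
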