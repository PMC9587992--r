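Package: tlaphaser
Title: Simulation, Split-Read Mapping and Link-Based Phasing of Targeted
    Locus Amplification Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying haplotype phasing with Targeted Locus
    Amplification (TLA) sequencing. TLA crosslinks DNA in physical
    proximity, digests it with NlaIII, and circularises the fragments so
    that distant variants from a single homologous chromosome end up on
    one sequenced molecule. The package provides an in-silico TLA read
    simulator (restriction digestion, haplotype-pure proximity-ligation
    circles with distance-decay contact probabilities, viewpoint-anchored
    PCR amplicons, short paired-end and long single-molecule read models),
    an iterative split-read mapper that cuts chimeric reads at NlaIII
    recognition sites, depth-filtered variant calling from fragment
    pileups, read-backed phasing from allele co-occurrence links, and
    genotype/phasing concordance benchmarking including switch errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'split-mapper.R'
    'pileup.R'
    'phaser.R'
    'benchmark.R'
    'locus-model.R'
    'simulator.R'
    'pipeline.R'
    'tlaphaser-package.R'
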