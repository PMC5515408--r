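Package: eboxscape
Title: E-Box Binding Specificity Analysis for bHLHZ Dimers
Version: 0.9.0
Authors@R:
    person("Regulatory", "Genomics Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the DNA-binding specificity of E-box-binding
    basic helix-loop-helix leucine-zipper dimers such as MYC:MAX and MAX:MAX.
    Implements custom protein-binding-microarray (PBM) probe design and
    empirical-null scoring, hexamer motif ranking and position weight matrix
    construction, genome-normalized motif-frequency enrichment over ChIP-seq
    peaks and summits with protein-dose comparisons, and equilibrium
    competitive-binding models for EMSA relative-affinity estimation. A
    synthetic-data layer generates genomes with planted motif sites of tiered
    affinities, dose-dependent peak calls, replicated array intensities and
    competition curves with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
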