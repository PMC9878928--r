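Package: zfintegrate
Title: Differential CTCF Binding, Gene-Peak Pareto Integration, Flank Motif
    Signatures and Aggregate Peak Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing acute depletion of the chromatin organiser
    CTCF and of its zinc-finger mutants. Implements reproducible-peak
    filtering with confidence tiers, fragment counting over peaks, spike-in
    and TMM normalisation with a moderated t differential test, gene-peak
    integration of expression and binding changes by combined z-scores and
    Pareto non-dominated sorting, PWM scanning with exact score p-values and
    flanking-sequence signature analysis (hamming-distance clustering,
    information-content logos), and aggregate peak analysis (P2LL) of binned
    contact maps against loop calls. Ships a synthetic-data generator that
    emulates the statistical structure of such experiments so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2
Config/testthat/edition: 3
biocViews: ChIPSeq, DifferentialPeakCalling, Epigenetics, HiC,
    MotifAnnotation, Normalization, Software
RoxygenNote: 7.3.3
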