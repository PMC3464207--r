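Package: spliceScreen
Title: Differential Cassette-Exon Splicing from Exon-Junction Microarrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection of differential cassette-exon splicing from
    exon-junction microarray probe intensities via a normalized splicing
    index (I_norm) with tiered probe-set voting, together with the
    surrounding analyses of a splicing-factor mutant screen: RMA-style
    preprocessing (normexp background correction, quantile normalization,
    median-polish summarization), RT-PCR-style exon inclusion rates and
    fold-change calls, polypyrimidine-tract scanning and ZOOPS-EM motif
    discovery in 3' splice-site-proximal intron windows, gene-level
    differential expression with gene-set overrepresentation, and
    single-deletion breakpoint mapping between wild-type and mutant
    genomic sequences. A seeded simulator generates every input with
    known truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: AlternativeSplicing, Microarray, Preprocessing,
    DifferentialSplicing, MotifDiscovery, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
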