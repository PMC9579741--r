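Package: CompositionMap
Title: Library-Type Quality Control from Per-Position Base Composition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summarises the per-position base composition of sequencing
    libraries (the leading positions of read1), places each library on a
    two-dimensional UMAP reference map built from a database of labelled
    composition profiles, and reports the percentage of each library type
    found in the map tile the query lands in. The tile percentages are an
    early, pre-mapping quality-control signal for sample swaps and library
    preparation irregularities. Includes a synthetic-signature generator
    that emulates the composition signatures of common protocols
    (bisulfite C depletion, Tn5 start bias in ATAC-seq, ChIA-PET linker,
    genomic ChIP baseline, random-priming RNA-seq) so the full pipeline
    can be exercised without downloading public data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    uwot,
    jsonlite,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: QualityControl, Sequencing, Preprocessing, DimensionReduction
RoxygenNote: 7.3.3
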