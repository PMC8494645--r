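Package: merfishAtlas
Title: Spatially Resolved Cell Atlas Construction from Multiplexed FISH Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for building spatially resolved cell
    atlases of cortical tissue from multiplexed error-robust FISH (MERFISH)
    style measurements. Provides constant-weight error-correcting codebook
    design and decoding, marker-gene panel selection by mutual information
    and differential-expression cover, encoding-probe design, pixel-based
    decoding of multi-round image stacks with blank-barcode
    misidentification control, seeded-watershed cell segmentation, a
    quality-control cascade (volume, batch and quantile filters plus
    simulated-doublet removal), two-round graph-based clustering with
    marker routing, laminar cortical-depth statistics, gradient and
    diffusion-pseudotime analysis of intratelencephalic neurons, and
    retrograde-tracer projection mapping. A fully seeded synthetic-data
    generator emulating the statistical structure of cortical MERFISH
    experiments makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    BiocNeighbors,
    Biostrings,
    EBImage,
    igraph,
    irlba,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Spatial, Transcriptomics, SingleCell, Clustering, QualityControl
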