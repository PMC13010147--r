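Package: riboCatalog
Title: Building and Scoring Catalogs of Non-Canonical ORFs from Ribo-Seq P-Site Tracks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assembling reference catalogs of translated
    non-canonical open reading frames (ncORFs) from ribosome profiling
    data. Candidate ORFs collected from multiple studies are collapsed,
    mapped to a transcript annotation, classified into the seven standard
    ncORF types (uORF, uoORF, intORF, dORF, doORF, lncRNA-ORF, PT-ORF),
    and scored against pooled P-site coverage tracks with three
    translation-signature metrics: P-sites in frame (PIF), Uniformity,
    and Drop-off. Pass thresholds are calibrated from annotated coding
    sequences, and ORFs passing in any dataset form a high-confidence
    Primary set within the Comprehensive catalog. A seeded simulator
    generates toy genomes, annotations, planted ORFs and P-site tracks
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'calibration.R'
    'coordinates.R'
    'psite-tracks.R'
    'signatures.R'
    'catalog.R'
    'constructors.R'
    'simulate.R'
    'cli.R'
    'riboCatalog-package.R'
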