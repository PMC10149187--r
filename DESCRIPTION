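Package: spatview
Title: Computational Backend for Interactive Viewing of Large-Scale
    Spatial Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Server-side building blocks for a multiresolution spatial
    omics viewer: Deep Zoom image pyramid construction and tile serving,
    memory-efficient columnar ingestion of large marker tables from CSV
    and HDF5/AnnData files, GeoJSON region geometry with fast
    point-to-region assignment, packed 32-byte-per-marker render-buffer
    emulation with chunked uploads, and the viewer's analytics: region
    histograms, neighborhood enrichment permutation tests, marker
    clustering into molecular regions, feature-space gating, and
    two-classifier confusion matrices. A deterministic synthetic-scene
    generator provides images and marked point processes for testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    jpeg,
    tiff,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sp,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'fixtures.R'
    'markerstore.R'
    'project.R'
    'pyramid.R'
    'regions.R'
    'renderprep.R'
    'server.R'
    'spatialstats.R'
    'spatview-package.R'
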