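Package: cytogate
Title: Automated Hierarchical Gating of Flow Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automation-first framework for hierarchical 1D/2D gating of
    large batches of flow cytometry standard (FCS) files. Provides an FCS
    2.0/3.0/3.1 reader and FCS 3.1 writer, spillover extraction and
    compensation, Logicle and Bilog display transforms, data-driven gating
    primitives (density-valley thresholds, shortest-path valley separation,
    Gaussian-mixture and principal-component ellipse gates) alongside static
    shapes, deterministic batch execution over sample cohorts, and
    image-clustering plus percentile-based quality control. Ships a synthetic
    cohort generator with known ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    parallel,
    cluster,
    mclust,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
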