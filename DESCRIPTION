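Package: mriscreen
Title: Snapshot-Based Quality Review for Processed Multimodal Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch quality-control screening for processed multimodal brain
    MRI studies and their annotations. Pre-renders static key-slice snapshot
    panels (segmentation overlays at maximum-area slices, registration checks
    with a shared brain-mask overlay, CSF-ROI confirmation views, scaled
    intensity density plots, and crosshair views at the maximum-intensity
    tumor voxel), computes automatic screening metrics (normalized-intensity
    range checks, segmentation-outside-brain fractions, tumor volumes),
    manages a structured CSV review log with merging and a combined
    three-level quality classification, aggregates reviews into failure-rate
    tables and quality-stratified volume RMSE, and assembles a static HTML
    review gallery. A synthetic multimodal brain phantom cohort generator
    with injectable failure modes makes the whole pipeline testable without
    any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
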