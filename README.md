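# mriscreen

Batch quality-control screening for **processed** multimodal brain-MRI
studies and their annotations.

Pipelines that prepare brain-tumor MRI for quantitative analysis —
co-registration, skull stripping, intensity normalization, automatic tumor
segmentation — fail in ways that raw-image QC tools never see: a rotated
FLAIR, a brain mask clipping cortex, a segmentation spilling out of a
truncated field of view, intensities normalized onto the wrong scale.
Catching these requires a human looking at the *derived* data, and the
bottleneck is loading: minutes per study in an interactive viewer.

`mriscreen` front-loads that cost. For every study it pre-renders a small
set of static key-slice PNG panels — each annotation overlaid on anatomy at
the annotation's **maximum-area slice**, every modality with the brain mask
contour at *shared* slice indices so misregistration is visible, CSF-ROI
confirmation views, unit-peak intensity density curves against the expected
normalized range (default \[-5, 5\]), and crosshair views at the
maximum-intensity voxel inside the tumor ROI. Review then happens at a
glance, and the results live in a plain CSV log with a fixed schema.

On top of the log the package computes the standard accounting:

* per-category counts of *acceptable / minor errors (`poor`) / failure
  (`fail`)* for brain mask, registration, tumor segmentation and CSF
  localization, plus two-level image-quality and normalization flags;
* a combined per-study class by maximum severity,
  `failure > minor_errors > acceptable`;
* failure rates and acceptable fractions
  (`acceptable% = (acceptable + minor) / n`);
* volume agreement stratified by segmentation quality:
  `RMSE = sqrt(mean((V_measured - V_reference)^2))` per stratum, restricted
  to studies whose image quality, registration and brain mask are all
  clean so segmentation is the deciding factor.

A geometric multimodal brain-phantom generator with injectable failure
modes (misregistration, bias field, normalization break, cropped field of
view, corrupted segmentation, missing file) makes the entire pipeline
testable with no clinical data, and a static HTML gallery (searchable
index, per-case pages, measured-vs-reference volume scatter with identity
line) replaces the interactive dashboard with a serverless, file-based
equivalent.

## Worked example

```r
library(mriscreen)

co <- make_cohort(8, c(corrupt_seg = 0.25, cropped_fov = 0.25),
                  dir = file.path(tempdir(), "demo"), seed = 7,
                  shape = c(32L, 32L, 32L))
co$truth[1:3, c("study_id", "failure_mode", "true_total_cm3")]
#>   study_id failure_mode true_total_cm3
#> 1     S001  cropped_fov         66.744
#> 2     S002        clean         43.200
#> 3     S003  corrupt_seg         55.944

rec <- study_record(co$manifest, "S001")
snaps <- render_study(rec, file.path(tempdir(), "demo_snaps"))
snaps
#> <snapshot_set> S001: 19 panels (rendered=19)

compute_study_qc(rec, snaps)
#> <study_qc> S001: total 66.74 cm^3, enhancing 12.96 cm^3, outside-brain 0.680
#>   normalization flags: T1=FALSE T1C=FALSE T2=FALSE FLAIR=FALSE
```

S001 received a cropped field of view, and the QC pre-flag shows it: 68% of
its tumor segmentation falls outside the (truncated) brain mask, while its
intensity normalization is fine. Aggregating an oracle review of the
cohort's truth table:

```r
summarize_reviews(oracle_review(co$truth))
#> Review summary of 8 studies
#>            category acceptable minor_errors failure failure_rate_pct
#>       image_quality          6           NA       2             25.0
#>          brain_mask          8            0       0              0.0
#>        registration          8            0       0              0.0
#>  tumor_segmentation          5            0       3             37.5
#>    csf_localization          8            0       0              0.0
#>       normalization          8           NA       0              0.0
#> Review result: 3 acceptable / 0 minor errors / 5 failure
#> Acceptable quality: 3 of 8 (38%, 37.5%)
```

Every injected failure lands in exactly its review category, and the
combined result classifies each study by its worst finding. The same
machinery run on a review log of 1380 studies reproduces published-style
tables: failure rates at one decimal, acceptable fractions at the nearest
integer, and quality-stratified volume RMSE.

Build the browsable gallery with:

```r
qcs <- lapply(study_records(co$manifest), compute_study_qc)
build_report(co$manifest, file.path(tempdir(), "demo_snaps"),
             "site", qcs = qcs)
# open site/index.html in any browser - no server needed
```

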