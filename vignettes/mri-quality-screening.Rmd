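---
title: "Snapshot-based quality screening of processed brain MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot-based quality screening of processed brain MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriscreen)
```

## The problem

Quantitative analyses of brain-tumor MRI depend on a processing pipeline —
co-registration, skull stripping, intensity normalization, automatic tumor
segmentation — whose failures are individually rare but collectively common,
and mostly invisible to tools that only look at raw images. Reviewing
thousands of processed studies interactively is the bottleneck: loading a
multimodal study and its annotations into a 3D viewer takes minutes per
case.

`mriscreen` takes the opposite trade. All rendering cost is front-loaded: a
handful of informative 2D slices per study are rendered **once** as static
PNG panels, so review itself is just looking at pictures and ticking
structured boxes. A review is a row in a CSV file; aggregation, combined
quality classification, and volume-error stratification are ordinary
computations on that table. The package covers the whole loop: NIfTI
geometry, panel rendering, automatic pre-flags, the review-log data
contract, a static HTML gallery, and a synthetic phantom cohort that makes
every step testable without patient data.

## Geometry conventions

All volumes are NIfTI-1; the affine maps **0-based** voxel indices to world
mm (RAS+). Every public slice or voxel index in the package is therefore
0-based, and conversion to R's 1-based subscripts happens internally —
returned indices match what any other NIfTI tool would report.

Internally everything is reoriented to canonical RAS
(`reorient_canonical()`): axes are permuted and flipped so storage order is
Right, Anterior, Superior with positive steps, while the world coordinate of
every voxel is unchanged. Anatomical planes are then fixed by storage axis:
axial = third, sagittal = first, coronal = second. Reorientation requires
each storage axis to lie within 45 degrees of a cardinal direction; truly
oblique acquisitions are rejected rather than silently resampled, since the
toolkit reviews pipeline *outputs*, which are resampled to near-cardinal
grids.

Slices are displayed in radiological-style orientation: the patient's left
on the viewer's right, anterior up on axial slices, superior up on sagittal
and coronal slices. This is a convention, documented and centralized in one
helper, not a claim about the data.

Volumes are `|det|` of the affine's upper-left 3x3 per voxel (mm^3), so
rotations of the grid cannot change a measured volume; label volumes are
voxel counts times that quantity, reported in cm^3.

## What gets rendered, and why these slices

For each study `render_study()` writes, deterministically
(`{study_id}_{kind}_{modality}_{plane}.png`):

* **Annotation overviews** — a three-plane overlay of each annotation
  (brain mask, three-label tumor segmentation, CSF ROI) on a reference
  anatomical image, at the annotation's own *maximum-area slices*: the
  slice with the most foreground voxels is the most informative single
  view of a segmentation. Ties break to the lowest index; an empty map
  falls back to the middle slice, a contract rather than an error, because
  an empty segmentation is precisely the kind of thing a reviewer must see.
* **Registration checks** — axial and sagittal views of every modality
  with the brain mask overlaid as a 1-pixel contour, at the *brain mask's*
  max-area slices. The same slice index is used on every co-registered
  modality, so a misregistered modality visibly disagrees with the shared
  contour.
* **CSF confirmation** — the CSF ROI on every modality at the ROI's
  max-area axial slice: the ROI must look like CSF on all sequences
  (bright on T2, suppressed on FLAIR).
* **Density panels** — per-modality intensity density curves within each
  segmented region, each curve rescaled to unit peak, with the expected
  normalized range (default [-5, 5]) marked. Unit-peak rather than
  unit-area scaling was chosen so that small regions (a CSF ROI of a few
  dozen voxels) remain visible next to the brain curve; the curves compare
  shape and location, not mass. Estimation is a 100-bin histogram with no
  kernel smoothing: deterministic, cheap, and artifacts are not smoothed
  away.
* **Crosshair views** — for functional/derived maps, a three-plane view
  centered on the maximum-intensity voxel inside the tumor ROI
  (lexicographically smallest on ties), showing whether extreme values are
  biology or artifact.

Display windowing uses the 1st–99th percentile of within-brain intensities
per slice (whole slice if no mask): robust to exactly the hot voxels the
dashboard exists to surface. The palette is fixed and color-blind aware:
yellow brain-mask contour, red/green/blue tumor labels by ascending label,
cyan CSF, overlay alpha 0.4.

Panels are composed as numeric arrays and written with `png::writePNG`, so
re-rendering a study is byte-identical — there is no font, antialiasing or
device nondeterminism in the raster path. The review site's scatter plot is
ordinary base graphics, where no such guarantee is needed.

## Automatic pre-flags

`compute_study_qc()` computes advisory quantities shown beside the panels;
they never auto-fill the human review:

* **Normalization check**: robust low/high (0.5th/99.5th percentile) of
  within-brain intensities against the expected interval. Percentiles
  rather than min/max tolerate isolated extreme voxels; the 0.5% tail width
  is the package's operational definition of "a few outliers".
* **Segmentation outside brain**: the fraction of tumor-segmentation
  voxels on brain-mask background — nonzero for truncated fields of view
  or escaped segmentations; exactly 0 for an empty segmentation.
* **Tumor volumes**: total (all nonzero labels — the package's reading of
  total T2-FLAIR hyperintensity, configurable via the label-role map) and
  enhancing (the label with role `enhancing`; *absent*, not zero, if no
  label has that role).
* **Missing inputs / missing panels**: expected-but-absent files, feeding
  the reviewer's "No PNGs" flag.

No automatic misregistration score is computed: registration is checked
visually via the shared-contour panels, and that boundary is deliberate.

## The review log and its aggregation

A review entry records a three-level call (`acceptable` / `poor` / `fail`)
for brain mask, tumor segmentation, CSF ROI and registration, six boolean
flags (`study_artifact`, `image_unusable`, `bias_field`,
`normalization_failure`, `no_pngs`, `needs_review`), a free CSF-location
string and a comment. `poor` means minor errors unlikely to affect
downstream processing; `fail` means unusable. The CSV schema (RFC 4180,
fixed column order, booleans as 0/1) is the source of truth: there is no
server state, and `merge_logs()` resolves concurrent review by
later-timestamp-wins with deterministic tie-breaks, which is why timestamps
are assigned in UTC at entry creation.

The combined study class is maximum severity: any `fail` or any
failure-severity flag (`study_artifact`, `image_unusable`,
`normalization_failure`) makes the study a failure; otherwise any `poor` or
minor-severity flag (`bias_field`) makes it minor-errors; otherwise
acceptable. `no_pngs` and `needs_review` gate completeness, not quality.
Two choices here were genuinely open and are configurable: bias-field is
treated as minor by default (a visible bias field that survives processing
usually degrades rather than destroys), and the flag-to-severity map can be
rebound per project. Image quality and normalization are two-level
categories (acceptable/failure only) in summaries.

`summarize_reviews()` tallies the per-category and combined counts —
revalidating on every call that each category's counts sum to the log size
— and reports failure rates at one decimal and acceptable fractions at the
nearest integer, matching how such tables are conventionally printed.

`rmse_by_quality()` stratifies volume error by the *tumor-segmentation*
category, not the combined class, and by default restricts to studies whose
image quality, registration and brain mask are all clean, so that
segmentation quality is the only deciding factor in the comparison. RMSE is
reported per stratum with its n; empty strata report an absent RMSE rather
than being dropped.

Because published review tables report only margins (per-category counts
and a combined split), `review_log_from_counts()` reconstructs *a* log
realizing all requested margins jointly: failure marks are packed
cyclically onto the combined-failure pool, poor marks onto the minor pool
with spill onto failure studies, skipping same-category conflicts, and the
result is revalidated against every requested count. Co-occurrence beyond
the margins is unidentifiable from such tables and is not claimed; any
consistent packing gives identical summaries because all summary statistics
are functions of the margins.

## The synthetic cohort

`make_phantom_study()` writes a fully synthetic processed study: an
ellipsoidal brain (semi-axes 78/90/66 mm), a three-compartment concentric
tumor (necrotic core 8 mm, enhancing rim 15 mm, edema 24 mm by default), a
ventricle sphere with a CSF ROI, four co-registered modalities with
tissue-dependent contrast (enhancing bright on T1C, edema bright on
T2/FLAIR, CSF bright on T2 and suppressed on FLAIR), Gaussian noise,
z-score normalization within the brain mask, and background fixed at 0
(the skull-stripped convention). Contrast-to-noise is calibrated so clean
in-brain z-scores sit within the expected [-5, 5] interval with a robust
high around 3 — as they do in real normalized data — leaving headroom so
that only genuine degradations trip the range check. Every draw is fixed by
the seed; regeneration is byte-identical, and a truth JSON records exact
label voxel counts.

`inject_failure()` degrades exactly one artifact per study: rigid in-plane
misalignment (10 degrees plus a 10/5 mm offset — the brain is nearly
circular in-plane, so rotation alone would be nearly invisible, as it is
for real heads), a smooth multiplicative bias field (amplitude 0.3), an
intensity scale blow-up (x100), a truncated field of view (top 35% of
axial slices zeroed in images and brain mask while the tumor map is left
intact, so the segmentation exits the brain), a shifted-and-dilated tumor
segmentation constrained to the brain (inflating measured volume while the
truth file keeps pre-corruption volumes), or a deleted modality file. Each
mode maps to exactly one review category, which keeps cohort truth labels
unambiguous; `make_cohort()` therefore assigns at most one mode per study.

What the phantom does *not* emulate: anatomy is geometric, noise is
Gaussian rather than Rician, there is no k-space artifact model, and
segmentation "errors" are rigid geometric corruptions. Passing tests
demonstrate that the accounting, rendering and aggregation machinery is
correct under controlled failures — not that human reviewers or upstream
segmentation models behave well on clinical data.

## Problem sizes and numerical choices

The test suite and the acceptance script run phantoms at 32^3 (6 mm
spacing, same physical anatomy as the 64^3 / 3 mm default) and a 60-study
cohort with three failure modes at rate 0.2 — sizes chosen so the full
pipeline, including file I/O for several hundred NIfTI volumes, exercises
every code path in well under a minute. The normalization-statistics check
uses one 64^3 phantom, where within-brain mean and sd are 0 and 1 to well
below 0.05 by construction.

Degenerate inputs are contracts, not errors, wherever a reviewer needs to
see the case: empty segmentations fall back to middle slices and zero
volumes, NaN voxels are replaced by the image minimum with a warning,
non-integer label values are rounded with a warning, and missing files
produce skipped panels and QC notes rather than aborting a study. Errors
are reserved for malformed geometry (shape mismatches, singular or oblique
affines) and schema violations, each with a distinct condition class.

## Known limitations

* Key-slice review can miss artifacts confined to unrendered slices; that
  trade (speed for completeness) is the design premise, not an oversight.
* The combined classification's flag-severity map is a modeling choice
  where source tables are ambiguous; it is configurable and documented.
* The static gallery has no in-browser review entry; reviews are edited as
  CSV or via the CLI, keeping the artifact serverless.
* Oblique volumes are rejected, not resampled.
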