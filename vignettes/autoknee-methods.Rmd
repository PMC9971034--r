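---
title: "autoknee: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{autoknee: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Customising a total knee replacement (TKR) implant to a patient normally
requires manual segmentation of a CT stack and bespoke CAD work.
`autoknee` implements an automated alternative: from an axial CT DICOM
series and a knee-side flag it (i) classifies every slice into
FIBULA_TIBIA / KNEE / FEMUR / OTHER, (ii) locates a fixed 160 x 160 px
region of interest around the (left-convention) knee, (iii) segments the
femur and tibia per slice, (iv) assembles per-slice bone contours into
3-D contour stacks split at an automatically detected tibia-femur
transition, (v) fits a per-bone statistical shape model (SSM) to each
stack to predict the full 3-D bone surface, (vi) derives a generic
femoral component and tibial plate from the predictions, and (vii) scores
fit by surface RMSE and maximum over/underhang (OUH).

Clinical CT corpora with segmented ground-truth meshes are restricted, so
the package carries a parametric knee phantom generator that emulates the
relevant properties of such data (0.8 mm in-plane / 1 mm slice spacing,
distal femur + proximal tibia + fibula stub + patella + soft tissue,
per-slice labels, boxes and masks, corresponded ground-truth meshes).
Everything below the image-ingest layer trains and evaluates on these
phantoms at desk scale.

## Coordinate conventions

One convention is used package-wide: pixel `(row r, col c)` of slice `k`
(1-based in R) maps to millimetres as `x = (c-1) * spacing_col`,
`y = (r-1) * spacing_row`, `z = (k-1) * slice_spacing` relative to the
volume origin.  The canonical anatomical frame is a LEFT knee: `x`
medial-lateral (medial = +x), `y` anterior-posterior, `z` along the scan
axis increasing tibia to femur.  Right knees are mirrored at the image
level ("flip, then detect"), so a single left-knee detector and left
convention serve both sides; slice classification happens *before* the
flip and is trained on both orientations.  Slice ranges are 1-based and
inclusive.

## The synthetic knee phantom

Each bone is a capped tube mesh: rings of vertices stacked along `z` with
an analytic radius function, closed by flat fan caps.  All subjects
deform one template, so meshes are in exact vertex correspondence by
construction and the SSM's true dimensionality is known.

* **Femur** (z in [3, 45] mm): a condylar bulge that narrows into a
  shaft, two condyle lobes (`cos 2 theta` modulation, amplitude 0.35
  decaying proximally) and a posterior intercondylar notch (Gaussian
  angular notch, amplitude 0.28).  The notch matters twice: it is
  anatomically expected, and it is the per-slice feature that lets a
  slice-level model tell a femoral condylar section from a tibial
  plateau section.
* **Tibia** (z in [-39, -3] mm): a narrow shaft flaring (`t^4`) into the
  plateau; the proximal rings are tilted about the medial-lateral
  direction by the plateau-slope parameter (template slope 4 degrees).
* **Fibula** stub and **patella**: thin distractors.  The fibula
  exercises the FIBULA_TIBIA class and the tibia segmenter's
  specificity; the patella keeps joint-space slices visually "knee-like"
  (without it they would be indistinguishable from soft-tissue-only
  OTHER slices, which no per-slice classifier could resolve).

Three population modes with generator-default standard deviations:
global scale (dimensionless, sd 0.04 — about the spread of adult knee
widths relative to their mean), femoral condyle prominence (sd 0.05) and
tibial plateau slope (sd 3 degrees about the 4 degree template, matching
reported posterior-slope variability).  Vertex jitter is 0.1 mm.  Subject
metadata (sex alternating, age uniform 21-60, height coupled to the
scale mode) exists so the cohort statistics have realistic covariates.
These defaults were chosen once as the package's study conditions.

Volumes are voxelised at 0.8 x 0.8 x 1 mm (176 x 176 px, 104 slices) by
slicing each mesh per plane and scan-filling the polygons; stored
intensities are air 0, soft tissue 60, bone 220 with Gaussian read noise
(sd 8).  The phantom does **not** model cortical/trabecular texture,
osteophytes or metal artefacts; passing tests therefore demonstrate the
pipeline's mechanics and its geometry handling, not clinical-grade
segmentation robustness.

The ground-truth tibia-femur boundary is defined as the proximal-most
tibia point (where the plateau begins); transition detection is accepted
within 2 slices of it.

## Learned stages

The environment's deep-learning-free setting is embraced: each learned
stage is a compact single-hidden-layer network (`nnet`) over engineered
features, with the same contracts a CNN stack would carry (held-out
accuracy >= 0.95 for the classifier, mean centre error <= 5 px for the
box regressor, mean Dice >= 0.90 per bone for the segmenters).

* **Slice classifier**: 11 shape descriptors of the thresholded bone
  content (areas, component count, bounding box, centroid, eccentricity,
  soft-tissue fraction) -> 4-class softmax network.
* **ROI detector**: the same descriptors -> linear-output network
  regressing the normalised box centre.  Per-volume aggregation takes the
  per-axis *lower* median (determinism on even counts) and clamps the
  160 px window inside the image.
* **Bone segmenters** (one per bone): a presence gate (network over
  largest-component geometry features, where the intercondylar notch
  separates femoral from tibial sections) followed by an intensity
  threshold chosen to maximise training Dice and a
  largest-connected-component rule that rejects fibula and patella.

## Contours, transition, stacks

Contours are traced as the outer boundaries of connected mask components
(on a binary mask, gradient edge detection reduces to boundary tracing);
contours shorter than `min_contour_px` (default 20 px) are dropped as
segmentation noise, and inner hole contours are discarded.  Per-slice
segmented areas for both bones form the area profiles; the transition
slice is the **first** index between the two curve maxima (tibia maximum
first, in tibia-to-femur orientation) at which the femur area meets or
exceeds the tibia area, with ties resolving to that index — a
deterministic concretisation of "where the curves intersect".  The tibia
stack takes slices from `knee_first + trim` up to the transition, the
femur stack from the transition to `knee_last - trim` (trim default 5),
interpreting the trimmed ends as the knee-region boundaries where
end-of-region segmentation noise concentrates.

## Statistical shape models

`shape_model()` performs generalised Procrustes alignment (rigid only —
no scaling, so absolute size is carried by the modes, which is why the
synthetic population includes an explicit scale mode) followed by PCA of
the aligned vertex coordinates.  The base (mean) shape may be
Laplacian-smoothed (`smooth_iters`, default 2 in the pipeline) to give an
idealised surface for implant design; modes are always computed from the
unsmoothed data, so full-mode reconstruction of training meshes is exact
to numerical precision when smoothing is off.

Alignment of a contour stack to the base shape initialises from anatomy
— in-plane centroids matched, and the anatomically informative stack end
(femoral stacks start at the condyles, tibial stacks end at the plateau)
matched to the corresponding end of the base shape, keeping `z` as the
slice normal — then refines by rigid ICP.  The in-plane rotation is
assumed small (axial acquisition of a supine patient); ICP absorbs the
residual.  ICP uses point-to-plane steps (linearised rotation solved in
closed form against closest-point facet planes) with a point-to-point
Kabsch fallback, which converges in a handful of iterations where pure
point-to-point needs hundreds; the recorded RMS history is non-increasing
by construction and the best iterate is returned.

Morphing fits only the first `n_pc = 2` principal components: the
closest-point correspondence fixes barycentric footpoints on the current
surface, the weights then solve a small linear least-squares problem,
and the two steps alternate until the objective (mean squared
closest-point distance) stops improving.  Weights are clamped to +/- 3
mode standard deviations to prevent extrapolation; correspondences more
than 2.5x the median distance away (residual segmentation debris) are
trimmed from the solve.  Restricting to two components is what makes the
prediction robust to local segmentation imperfections — the model can
only move along its two strongest population modes.

## Implant design

All design operations are deterministic mesh geometry:

* **Femoral component**: the condylar AP/ML extents (bounding box of the
  lowest 45% of the prediction's z extent) scale a five-plane cut
  template (anterior, anterior chamfer at 45 degrees, distal, posterior
  chamfer, posterior; offsets are fixed fractions of AP — package
  defaults, editable as plain data).  The solid prediction is clipped by
  each plane with the cut capped, keeping the distal piece watertight;
  two cylindrical fixation pins (radius 3 mm, length 10 mm) are added on
  the bone-facing side as separate mesh parts so metrics can exclude
  them.  The component "edges" for the OUH metric are the outlines of
  the cut facets.  The inward shell offset is folded into the solid
  slab; `shell_mm` (default 1) remains the bone-facing tolerance used by
  the self-fit contract.  Fillets and chamfer rounding are omitted: they
  do not move the evaluated surfaces or edges.
* **Tibial plate**: a least-squares plane through the plateau facets
  (upward-facing faces in the top fifth of the z extent), oriented
  distally; the section plane passes 2 mm distal to the widest
  medial-condyle point; the largest section loop becomes the base
  profile, which is extruded 5 mm, given a posterior chord cut, a
  central rectangular bearing recess (depth 2 mm) and a central fixation
  pin.

Resection applies the *same* plan (femur) or the *same* section plane
(tibia) to the ground-truth bone, after the ground truth is first
brought into the component's design frame by whole-bone rigid ICP onto
the stored source prediction — this makes every fit report invariant to
rigid motion of the ground truth, and makes self-fit (ground truth =
prediction) exactly clean.

## Fit metrics

* `surface_rmse()` samples the prediction surface (area-weighted, seeded)
  within the fitted z band — the region covered by the contour stack,
  which is the package's concretisation of "the condylar region" — and
  takes root-mean-squared closest-point distances after optional rigid
  ICP.
* `max_ouh()` is the directed Hausdorff distance from component edge
  points to resected-bone edge points, computed exactly; the clinical
  flag is inclusive at 3 mm and config-overridable.
* Femoral component fit excludes the pins and compares against the
  equivalently resected ground truth; tibial fit compares the 2-D base
  profile to the equivalent ground-truth profile after rigid 2-D
  alignment (the plate interfaces with the bone on one face only).
* `cohort_stats()` uses Welch two-sample t-tests (chosen over the pooled
  test since group variances are not assumed equal) after 1.5 x IQR
  outlier removal — an automatic stand-in for manual quantile-quantile
  inspection — and Spearman correlations for continuous covariates;
  significance at p <= 0.05 and |r| >= 0.5.

## Numerical choices and degenerate inputs

Plane slicing nudges the plane by 1e-6 mm off exact vertex hits and
computes crossing points in canonical edge order so shared edges chain
exactly.  Mesh clipping treats on-plane vertices as kept and caps cut
rims by centroid fans (cross-sections here are star-shaped).  Polygon
rasterisation uses even-odd scanline filling at pixel centres.  The
even-count median ROI takes the lower median.  Ear-clipping triangulation
backs the plate faces, with a nearest-vertex bridge for the recess
annulus.  Degenerate inputs error early with stage-specific messages
("no usable series", "class coverage", "no knee region", "stack too
short", "degenerate cut plan", "FOV overflow"), and `run_pipeline()`
converts any stage error into a diagnostic `pipeline_failure` object
naming the stage rather than crashing.

## Problem sizes

The package's reference experiment — used by the test suite and by
`scripts/acceptance.R` — trains on a 20-subject phantom population
(80/20 subject-level split), evaluates 10 held-out phantoms end to end,
checks transition detection on 50 phantoms via oracle masks, and checks
ICP recovery on 20 random rigid transforms with rotations up to 20
degrees.  These sizes give stable statistics for every contract while
keeping a full run in the minutes range on a single CPU.

## Known limitations

* The phantom geometry is smooth and three-mode; it cannot expose
  failure modes caused by pathology (osteophytes, holes), imaging
  artefacts or unusual anatomy.
* The learned stages are feature-based stand-ins with CNN-equivalent
  contracts; on real CT they would need to be replaced by trained
  networks behind the same interfaces.
* The femoral cut template's offsets and pin dimensions are package
  defaults, not published implant dimensions.
* Sub-slice transition interpolation, multi-frame DICOM, gantry tilt and
  non-axial reformats are out of scope.
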