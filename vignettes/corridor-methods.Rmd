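---
title: "Measuring the infra-acetabular screw corridor on 3D bone models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the infra-acetabular screw corridor on 3D bone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iacorridor)
```

## The measurement problem

The infra-acetabular corridor (IAC) is the narrow bony channel running
beneath the acetabulum from the superior pubic ramus region to the
ischium. A screw placed along it closes the periacetabular fixation
frame, linking the anterior and posterior columns, which biomechanical
work has shown adds substantially to the stability of column-spanning
acetabular fracture fixation. The channel is tight — a 3.5 mm screw is
the clinically relevant size, and in a large fraction of hips no such
screw fits at all — and its effective width depends strongly on the
direction from which it is viewed and drilled. Intra-operatively that
direction is set by the fluoroscopic angle: the C-arm's forward (inlet)
tilt away from the plain anterior–posterior view.

`iacorridor` implements this measurement as an automated pipeline on
segmented bone models:

1. **frames** — build the anatomical reference frames (anterior pelvic
   plane, sagittal midline plane) from three bony landmarks;
2. **corridor** — for a given fluoroscopic angle, search the azimuth
   about the pelvis' vertical axis for the view that exposes the
   largest corridor, and measure the maximal intra-osseous screw
   cylinder in that view;
3. **stats** — apply the 3.5 mm cutoff and run the cohort statistics
   (insertion rates, sex comparisons, per-angle ANOVA with post-hoc
   contrasts, anthropometric correlations);
4. **phantom** — generate synthetic bone models with analytically known
   corridor geometry, and synthetic cohorts, so the whole pipeline is
   testable without any imaging data.

## Anatomical frames

The anterior pelvic plane (APP) is the plane through the left and right
anterior superior iliac spines (ASIS) and the pubic symphysis (PS); it
is the standard coronal reference for the supine pelvis. From the three
landmarks we build a right-handed orthonormal triad: `ml_axis` from the
left to the right ASIS; `si_axis` in-plane from the PS towards the ASIS
midpoint; `ap_axis = si × ml`, the APP normal, pointing anteriorly. The
sagittal midline plane (SMP) passes through the PS and the ASIS
midpoint with normal `ml_axis`; it is perpendicular to the APP by
construction. Only the three stated landmarks enter, so the frames are
exactly reproducible and equivariant under rigid motion of the subject.

The APP-vs-table angle (`app_table_angle`) quantifies whether the APP
is a usable reference in the scanner pose: it is 0 when the APP is
perpendicular to the table's horizontal plane and grows with forward
pelvic tilt (`asin(ap_axis · table_up)` in degrees). Published cohorts
report a near-zero mean for supine patients but do not state the sign
convention, so it is an argument (`sign_convention`), with
forward-positive as the default.

A fluoroscopic view is parameterized by the fluoroscopic angle `alpha`
(rotation of the beam from the AP view about `ml_axis`, towards an
inlet view — for `azimuth = 0` the beam makes exactly `alpha` degrees
with the APP normal) followed by the azimuth (rotation about
`si_axis`, the pelvis' vertical axis). The order mirrors the manual
procedure: tilt the pelvis forward by `alpha`, then turn the beam about
the vertical axis. Whether the azimuth should instead be taken about
the scanner vertical is not determinable from the source material; the
body-fixed `si_axis` is used because it keeps the scan symmetric for a
symmetric pelvis.

The corridor's direction is summarized by the AIP, the signed angle
between the screw axis and the SMP. The axis is oriented
anterior-to-posterior and the sign is side-aware: positive when the
axis runs anteromedial→posterolateral (the posterior end farther from
the midline on the measured side). This makes left and right hips
directly poolable, at the price of a convention: a mirrored axis on the
mirrored side has the same AIP.

## The corridor search

### Ray-safety projection

`ray_safety_map` casts a bundle of parallel rays through the binary
occupancy volume along the viewing direction. A ray is *safe* iff its
bone intersection is a single contiguous interval of length at least
`min_len` with no internal air gap longer than `gap_tol` (default 0: a
screw that exits and re-enters bone has breached cortex by
definition). The safe pixels form the bright "U-shaped" region a
surgeon sees when the rendered pelvis is made semi-transparent; the
surrounding dark rim is superimposed cortex. `min_len` defaults to
40 mm — roughly half the shortest corridor lengths seen in adult
cohorts (~76 mm) — which suppresses grazing trajectories without ever
approaching a real corridor. The projection pixel pitch defaults to
half the smallest voxel spacing and rays are marched at the same step
(Nyquist for the grid).

Occupancy is sampled by trilinear interpolation of the binary grid,
thresholded at 0.5. This places the effective bone surface within
about a quarter voxel of the true surface independently of
orientation. (Nearest-voxel lookup, the obvious alternative, erodes
surfaces by up to half a voxel *diagonal* and makes measurements
orientation-dependent — enough to violate the package's own
rigid-invariance tolerance at 1 mm voxels.)

### Largest inscribed disc

Within the safe mask, the projected cross-section of the widest screw
is the largest inscribed disc. `max_inscribed_disc` computes it from an
exact Euclidean distance transform (`EBImage::distmap`, verified exact
against brute force) on the mask padded with an unsafe border, after
connected-component labelling (`EBImage::bwlabel`). The continuous
radius is `(d − 0.5) · pitch` where `d` is the distance (in pixels) to
the nearest unsafe pixel centre: a single safe pixel admits a
half-pitch disc. Ties are broken towards the component centroid, then
in row-major pixel order, so results are deterministic. A `seed_hint`
restricts the search to one connected component; without it the
component holding the globally maximal disc wins.

### Verification and the diameter

The inscribed disc is only an upper bound on the screw diameter: its
rays are individually safe but need not share a common depth interval
(ray bundles can thread opposite ends of a biconical channel).
`verify_cylinder` is therefore the acceptance oracle for every
reported corridor: it samples the full cylinder — interior and
boundary surface, at half-voxel pitch (denser under `oversample`) —
and requires every sample to lie in bone. The reported IAD is the
largest diameter that passes, starting from the disc estimate and
backing off in half-pixel steps. The cylinder's axial span is inset by
0.75 voxel from the marched entry/exit depths, which is exactly the
depth uncertainty of the ray marching (half a marching step plus half
a voxel); the IAL is still reported as the raw entry-to-exit length of
the central ray, matching how a placed screw's intra-osseous length is
read off. `grow_cylinder` implements the literal bedside procedure —
start at 1 mm and enlarge until breach — and serves as an independent
cross-check of the distance-transform route; the two agree to a voxel
on random phantoms.

### Azimuth optimization

`optimize_corridor` scans the azimuth over ±30° in 1° steps (the AIP
range seen in adult cohorts spans only about −2° to +9°, so ±30° is
generous). The scan objective is the *projected corridor volume*: the
sum of intra-osseous lengths over safe rays. This is the quantitative
form of the manual rule — turn the beam until the largest bright area
appears — and it is exactly symmetric about the channel-aligned
azimuth for a symmetric channel.

The objective's shape dictates the refinement strategy. For a
biconical channel the *diameter* is flat in azimuth to first order
inside the channel's opening cone (a cylinder tilted by δ loses only a
factor cos δ of diameter: 0.0006 mm at δ = 1°), so no diameter-based
argmax can localize the azimuth; the volume objective is flat-topped
too, but its *edges* are sharp. `optimize_corridor` therefore finds
the contiguous near-maximal plateau (`plateau_frac`, default 90% of
the maximum) containing the grid optimum: if the plateau is narrow the
peak is sharp and a golden-section refinement to 0.1° is used; if it
is wide, the azimuth is the plateau midpoint, with the plateau edges
located by linear interpolation of the threshold crossings. On the
reference bicone phantom this recovers the true azimuth to well within
a degree, and the AIP to a few hundredths of a degree.

`side` only affects the AIP sign: the azimuth scan is symmetric and
the safety projection is side-agnostic, so no reflection of the volume
is needed for right hips. With `restarts > 1` the whole search is
repeated with a jittered azimuth grid and the maximum diameter kept,
emulating repeated manual measurements that retain the maximum;
default is a single deterministic pass.

## The phantom

Real corridor measurements cannot be reproduced without imaging data,
so the package's accuracy claims rest on phantoms with analytic ground
truth. `make_channel_phantom` builds a solid in which the only bony
through-passage of corridor length is a channel of revolution — a
cylinder, or a bicone whose radius is smallest at mid-length (the
waist) and grows linearly to the ends, mimicking the IAC's biconical
constriction at the acetabular fossa. For a bicone, the maximal
inscribed full-length cylinder has exactly the waist diameter, which
is what the corridor engine must recover.

The channel is surrounded by an air moat and then a bony shell
(circular or square cross-section, `body_margin` thick), so the
channel boundary is a genuine cortical boundary; a transverse air
notch cut through the shell at mid-length makes every shell path
discontiguous, so the channel is the only safe passage at the default
`min_len`. (If `min_len` is set below half the channel length, shell
fragments can admit short safe rays; the defaults exclude this.)
Landmarks are synthesized at fixed offsets in the same scene, so APP
and SMP are exact by construction and frame errors cannot masquerade
as corridor errors. An optional spherical `breach` carves a cortical
defect on the channel surface; a defect deeper than the waist radius
transects the channel entirely.

The phantom's ground truth (`PhantomTruth`) is invariant under rigid
re-posing of the scene (`rotation`/`translation` arguments), which the
tests exploit. What the phantom does *not* emulate: anatomical pelvic
shape, cortical/trabecular density structure, segmentation noise, or
asymmetric channel cross-sections. Passing the phantom tests therefore
demonstrates the geometry engine is correct, not that segmentation of
real CTs is accurate.

The voxelizer samples the analytic solid at voxel centres; at the
default 0.5 mm spacing the voxelized volume matches the closed-form
solid volume to well under 1%.

## The cohort emulator

`make_cohort` draws per-hip, per-angle tables under the study
conditions of a published adult cohort (94 male and 93 female
subjects, two hips each, five fluoroscopic angles), whose per-sex,
per-angle summaries ship as `iac_reference_params()` and whose
anthropometrics as `iac_reference_covariates()`. Choices that the
summaries do not determine:

* Corridor diameters are normal within sex × angle, truncated at 0 by
  resampling the hip-level innovation (the untruncated tail mass is
  below 1% at the reference summaries, so moments are essentially
  unchanged; censoring at 0 would create an artificial atom).
* The two hips of a subject share covariates but draw independent
  corridor values: the source cohort counts hips and reports no
  left–right coupling, so none is imposed (both counts are
  parameters, not constants).
* Height is coupled to diameter through a within-sex bivariate-normal
  construction, `z_iad = r·z_height + sqrt(1−r²)·ε`, which achieves
  the target Pearson r exactly in expectation *within* sex. Pooled
  over sexes the sample correlation also picks up the between-sex mean
  differences, so calibration checks measure the within-sex (or
  single-sex) correlation.
* BMI is derived from the generated height and weight (the cohort
  table's own consistency requirement); the reference BMI summary is
  kept for reference but cannot be honoured simultaneously.
* Ages are clamped to the published 18–65 range.

## Statistics conventions

The statistics stage reproduces the reference tables' conventions:
pooled-variance (Student) t tests by default (Welch optional), Pearson
chi-square *without* continuity correction — the only convention that
reproduces the published insertion-rate statistics (χ² = 28.85 from
139/188 vs 87/186, and 69.82 at 45°) — equal-variance one-way ANOVA
across angles treated as independent groups (as the source analysis
did, although the angles are repeated on the same hips), Tukey HSD
post-hoc contrasts by default with Bonferroni as the alternative
(which procedure produced the published stars is not stated), and the
inclusive 3.5 mm cutoff ("at least 3.5 mm"). Summary-based t tests use
the closed pooled form so printed group summaries can be re-tested
directly; raw-sample paths go through `stats::t.test`,
`stats::chisq.test`, `stats::oneway.test`, `stats::TukeyHSD` and
`stats::cor.test`. One arithmetic footnote: 226/374 = 60.428%, which
rounds to 60.43 even though the source table prints 60.42; the package
reports exact arithmetic.

`build_report` assembles the four standard tables (epidemiology;
per-angle per-sex summaries with insertion rates and tests; post-hoc
difference matrix, column-minus-row; correlation grid) as CSVs with a
fixed column contract, warning on missing angles or single-sex cohorts.

## Numerical choices and problem sizes

* Occupancy sampling: trilinear, threshold 0.5; surfaces localized to
  ~¼ voxel.
* Safety-map pitch and ray step: half the smallest voxel spacing.
* Disc radius: `(distance-transform − 0.5) · pitch`; ties towards the
  component centroid, then row-major.
* Azimuth scan ±30° step 1°; plateau fraction 0.9; golden-section
  refinement to 0.1° for sharp peaks.
* Verification span inset: 0.75 voxel; diameter back-off: half a map
  pixel per step.
* Degenerate inputs: no safe ray → `iad = 0` with a `no_corridor`
  flag (any safe ray, however small the region, is measured); zero
  variance in tests → flagged results rather than NaNs; collinear
  landmarks, zero-margin tables, non-watertight meshes → errors.

The test suite exercises the geometry at 1 mm voxels (seconds per
phantom) and reserves the 0.5 mm reference phantom — the conditions
under which the recovery tolerances of two voxels on IAD/IAL and one
degree on AIP are stated — for the acceptance checks; the resolution
sweep 1.0/0.5/0.25 mm demonstrates convergence of the recovered
diameter to the analytic waist. Monte-Carlo calibrations use 1000
two-sample null replicates, 100 ANOVA replicates (whose rejection rate
matches the closed-form noncentral-F power, 0.883, under the reference
male effect sizes at n = 188 — a detection standard of 95% is not
attainable from those effect sizes), and 200 generator round-trips for
the height–diameter correlation.

## Known limitations

* Binary occupancy only: no Hounsfield-weighted radiographic
  simulation; the "projection" is geometric, not radiometric.
* Straight cylinders only; no curved or multi-segment trajectories.
* The corridor azimuth is identifiable only up to the channel's
  opening cone when the objective is flat; the plateau-midpoint rule
  is exact for symmetric channels and approximate for asymmetric ones.
* The phantom is an abstract solid; no claims about segmentation of
  real CT data follow from phantom recovery.
* Landmarks must be provided; there is no automatic landmark detection.
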