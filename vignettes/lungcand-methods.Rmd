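---
title: "Candidate detection of lung nodules and ground-glass opacities: methods and design notes"
author: "lungcand developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lungcand methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungcand)
```

## The problem

Ground-glass opacities (GGO) are hazy regions of raised lung attenuation on
CT that do not obscure the underlying bronchovascular structures. Their
attenuation sits between aerated lung (about -850 HU) and soft tissue
(about 0-60 HU), well below that of blood vessels, which is exactly why
readers miss them. A computer-aided detection (CAD) pipeline for
nodules/GGOs has two halves: a *candidate generator* that proposes
locations with high sensitivity and tolerable false-positive load, and a
*classifier* that scores each candidate. `lungcand` implements the
candidate half end to end, plus the evaluation calculus, with a
deterministic geometric scorer standing at the seam where a trained model
(a CNN in the original formulation) would plug in.

## Pipeline stages and their parameters

### Parenchyma segmentation

Per axial slice: (1) threshold binarization at `hu_threshold` (default
-320 HU: aerated lung and air fall below, soft tissue above; the
literature this pipeline follows never states its threshold, so it is a
declared, configurable assumption); (2) removal of border-connected air
and retention of the largest interior component *together with every
component of at least 25% of its area* - a strict single maximum would
drop one lung whenever the two lungs are disconnected on a slice; (3)
hole filling, which re-absorbs airways, vessels and solid nodules into the
lung field; (4) contour refinement; (5) masking the volume to the
parenchyma (background set to -1024 HU).

Contour refinement is a closing ("mending") with a disk of
`mending_radius_mm` (default 4.5 mm) followed by an opening with a disk of
`erosion_radius_mm` (default 1.5 mm; "corrosion" then "expansion"). Two
geometric facts fix these choices, and both were confirmed empirically on
phantoms during development:

* a closing can only re-include a juxtapleural nodule of radius up to
  roughly its own disk radius, so 4.5 mm covers wall-attached nodules up
  to ~9 mm while staying below half the inter-lung gap (bridging the two
  lungs through the mediastinum begins at a disk radius of half the gap);
* the mending must run *before* the corrosion. A juxtapleural nodule
  carves a bay into the air mask framed by 1-2 px pleural "lips"; erosion
  destroys those lips first, after which no closing of sensible radius
  can recover the bay. With mending first, the default radii recover an
  8 mm juxtapleural nodule.

All morphology is 2-D per slice (the reference procedure is slice
oriented; 3-D structuring elements would behave differently at the lung
apices), with disk radii given in mm and converted through the in-plane
spacing, so behaviour is resolution independent.

### Candidate detection

Inside the mask, pixels with HU at or above `candidate_hu_min` (default
-750 HU - low enough to catch ground-glass attenuation) are labelled into
8-connected per-slice components. Components smaller than `min_area_px`
(default 9 px) are deleted ("small structures"), and components whose
moment-ellipse axis ratio exceeds `max_axis_ratio` (default 3.0) are
deleted ("thin long structures", i.e. near-in-plane vessels). Note the
geometry: a straight vessel tilted by an angle t from the axial normal has
an in-plane cross-section with axis ratio sec(t), so the default ratio
only removes vessels tilted beyond about 70 degrees. Oblique vessels at
30-60 degrees *survive* this filter by design - telling them apart from
nodules is precisely the job of the RGB superposition score downstream.

Before the search, the mask is eroded by `pleural_margin_mm` (default
1.5 mm) and the volume blanked outside it. The partial-volume band along
the pleura (attenuation between the candidate threshold and the
binarization threshold) otherwise produces a ring-shaped pseudo-candidate
on every slice and attaches itself to juxtapleural ROIs. Excluding a thin
pleural zone from the search is standard CAD practice.

Each surviving component contributes one candidate at its centroid, from
which a 64 x 64 x 3 ROI stack is cut (slices z-1, z, z+1; edge overhangs
padded with -1024 HU; at the first/last slice the missing neighbour is
replicated). The centroid sits at patch position 33 of 64. Candidates are
per-slice on purpose; a nodule spanning several slices yields several
candidates, which are merged later (see below).

### RGB superposition and the baseline scorer

The three ROI slices are windowed to bytes through a lung window (centre
-600 HU, width 1500 HU, configurable; chosen so that solid tissue and
GGO-range attenuation are foreground at the byte threshold 96 while lung
background at -850 HU, byte 85, is not) and assigned to the red (upper),
green (centre) and blue (lower) channels. A sphere's cross-sections are
concentric across three consecutive slices, so its channel foregrounds
coincide; an oblique tube's cross-section shifts by `dz * tan(tilt)` mm
per slice, so its channels separate. With the default 2.5 mm slice
spacing a 45-degree vessel of 2.5 mm radius shifts a full diameter per
slice and its triple intersection is empty.

`coincidence_score` quantifies the raw claim as the Jaccard overlap
`|R n G n B| / |R u G u B|` over the whole window, and is kept exactly at
that global definition (it is permutation-symmetric in the channels and
is what the contract tests pin down).

`baseline_score`, the deterministic stand-in for a trained classifier, is
measured on *the candidate's own structure*: the union-foreground
component containing the patch centre pixel defines the candidate region,
and the score is the fraction of that region that is channel-coincident,
times the compactness (`4 pi area / perimeter^2`, clamped to [0, 1]) of
the coincident core. Two design points deserve a record:

* An earlier draft multiplied the *global* coincidence by the compactness
  of the *global* intersection. That definition fails on its own terms the
  moment anything else coincident sits in the 44.8 mm window - lung-wall
  transition arcs inflated a 30-degree vessel to 0.54 while diluting a
  6 mm nodule to 0.05. Scoring the centre component makes the score about
  the candidate, not its neighbourhood; a hollow structure (a wall ring)
  has no foreground at its own centroid and scores 0.
* The known blind spot is geometric, not an implementation artifact:
  a *vertical* vessel (0 degrees tilt) overlaps across slices exactly like
  a sphere and scores high. The acceptance suite asserts this expected
  failure rather than hiding it. Separating vertical vessels needs
  cross-slice context longer than three slices, which is out of scope.

### Detection merging and evaluation

Because candidates are per-slice, `run_pipeline` applies an explicit
non-maximum suppression (`merge_detections`, radius 10 mm, keep the
highest score) between scoring and matching; without it every multi-slice
nodule would bill its extra detections as false positives under the strict
matching rule. Matching itself is greedy nearest-first in physical
coordinates with a hit radius of `max(diameter/2, 1.5 mm)`; each
annotation matches at most once, surplus detections are FP, unmatched
annotations FN.

The metric set follows the standard definitions: sensitivity/TPR
`TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity `TN/(TN+FP)`,
false-positive rate `FP/(TN+FP)`, `F = 2*precision*TPR/(precision+TPR)`,
accuracy, and average false positives per patient `FP / n_patients`.
Specificity and FPR are not printed in the source material; the forms used
here are validated against its printed values (TN 271, FP 29 give 0.903
and 0.097). A probability is called positive strictly above the threshold;
a score equal to the threshold is negative. Zero-denominator metrics are
`NA`, never 0 - zero-filling silently flatters extreme thresholds in
sweeps. Display rounding is half-up at the printed precision (one decimal
for percentages); internal values keep full precision.

Size-stratified reporting uses left-closed bins
`[3,5) [5,8) [8,10) [10,20) [20,Inf)` mm with an explicit `<3 mm`
overflow bin, and a closing `Total` row whose tallies the bins must sum
to.

## The phantom: what it emulates, and what it does not

The generator renders, in order: air background (-1000 HU), a soft-tissue
body ellipse (40 HU), two lung ellipsoids (-850 HU), an optional tracheal
air tube, straight cylindrical vessels clipped to their own lung, and
spherical nodules (solid at 30 HU; GGO strictly between lung and body
attenuation; juxtapleural nodules may protrude into the wall). Structures
are painted with a one-voxel linear partial-volume ramp whose surface
distance uses the gradient-normalized ellipsoid distance
`(1 - n)/|grad n|` (a naive `(1 - n) * min(axis)` misplaces the boundary
near the apices badly enough to cost a percentage point of Dice).
Gaussian i.i.d. noise in HU is added last; equal spec and seed give
bit-identical volumes. Ground truth is the set of lung-interior voxels
*before* structures are painted, plus one annotation per nodule.

Default geometry: 64 slices of 128 x 128 at (dz, dy, dx) =
(2.5, 0.7, 0.7) mm - deliberately thick-slice, since the tri-slice
encoding lives or dies by the slice spacing. The thorax is miniature
(90 mm across, lungs 27 x 48 x 120 mm): all length *ratios* that the
morphology depends on (nodule vs structuring element, vessel shift vs
radius) are realistic, but a 64 px window spans a third of this lung
rather than a fifth of a real one, which is why window-local scoring
matters more here than on real data. Other knowingly absent features:
curved and branching vessels, airway trees, lobe fissures, cardiac
motion, beam hardening, non-Gaussian noise. A green phantom test
establishes that the geometry and calculus behave as specified - not
clinical performance.

Preset design is frozen and documented in `default_test_spec()`:

* `easy` - 10 nodules, diameters 4-20 mm (solid, -500 HU GGO, one 8 mm
  juxtapleural), two oblique vessels (30 and 45 degrees). Nodule centres
  sit on slice centres; a sphere sampled off-centre in z can lose its
  upper or lower cross-section entirely at 2.5 mm spacing, which would
  test z-alignment luck rather than the method. The 4 mm nodule is
  *expected* to be missed by the scorer: with radius 2 mm < dz it appears
  on a single slice, so no tri-slice method can see it (candidate-level
  recall is only claimed at >= 5 mm). That one structural miss is why the
  preset has ten nodules: the end-to-end sensitivity criterion (>= 0.9) is
  meetable exactly when everything the method can physically see is found.
* `ggo-heavy` - >= 3 faint GGOs at 180 HU contrast (-670 HU), i.e. 4.5
  standard deviations above the default 20 HU noise inside the candidate
  threshold margin.
* `vessel-heavy` - vessels at 0/30/45/60 degrees (2.5 mm radius) in the
  left lung, three solid nodules (8/10/12 mm) in the right. Used by the
  separation criterion; 6 mm nodules are excluded here because at 2.5 mm
  spacing their adjacent-slice cross-sections are marginal and the
  criterion quantifies vessel-vs-nodule separation, not size limits.

## Numerical choices and degenerate inputs

* Voxel coordinates are 1-based `(slice, row, col)` throughout - this is
  R; the LIDC XML dialect's 1-based pixel coordinates are taken as-is.
* HU windowing rounds half-up; `round_half_up` is also used for report
  display (base R rounds half-to-even, which disagrees with the printed
  tables).
* Single-pixel components get `major = minor = 1` by convention; collinear
  multi-pixel components get ratio `Inf` and are always deleted by the
  elongation filter.
* Empty foreground unions, empty intersections, and probability ties at
  the decision threshold all resolve to the conservative side (score 0,
  negative call).
* DICOM series input is declared unsupported (no DICOM codec in the
  dependency set); the HU rescale contract (`stored*slope + intercept`,
  missing tags are an error, never an assumed identity) is exposed as
  `apply_hu_rescale`. NIfTI-1 and a plain-text raster-stack format cover
  volume I/O; the PNG codec for composites is implemented in-package
  (filter-0 writer, all-filter reader) because no PNG package is
  available either. All three are round-trip tested.
* Per-reader annotations are never merged at parse time; a
  union-of-readers view exists for evaluation only
  (`union_reader_annotations`, greedy 5 mm clustering).
* GGO selection defaults: texture rating <= 2 and internal structure = 1.
  The source material names the two characteristics but not its cut-offs;
  both are arguments.

## Known limitations

* The baseline scorer is a geometric stand-in: it separates oblique
  vessels from spheres but has no texture model, no malignancy notion,
  and a documented blind spot for vertical vessels. The
  `register_scorer`/`get_scorer` seam is where a trained model belongs.
* Sub-5 mm nodules are structurally invisible to the tri-slice encoding
  at thick-slice spacing.
* Phantom realism limits above; in particular noise is i.i.d. Gaussian,
  so streak or correlated noise behaviour is untested.
* The evaluation offers both ROI-level classification sweeps and
  nodule-level detection matching because the source material's negative
  counts imply per-ROI evaluation without stating it; both modes are in
  the report and tests exercise both.
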