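---
title: "Measuring planned-versus-achieved jaw segment movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring planned-versus-achieved jaw segment movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnathometry)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of a methods section: what is
computed, under which assumptions, and where the genuinely open design
decisions were made.

## The measurement model

Each osteotomized jaw segment (maxilla, distal mandibular segment, and
the two condyle-bearing proximal segments) is represented by an
ordered triangle of three cephalometric landmarks placed once on the
preoperative model:

* maxilla: mesial cusp 16, upper incisor, mesial cusp 26;
* distal mandible: mesial cusp 46, lower incisor, mesial cusp 36;
* proximal segments: condor, C-point, gonion (per side).

Because the same physical points are carried from state to state (by
the planning transform to the planned state, by rigid registration to
the postoperative state), comparing two states never re-identifies a
landmark, and identification error largely cancels out of the
planned-versus-achieved comparison. The motion between two states of
one segment is the least-squares proper rigid transform between the
corresponding triangles (Kabsch/SVD solution). A rigid-only model is
used deliberately: bone segments do not scale or shear between scans,
and the reported outputs are translations and rotations only. If the
SVD solution would be a reflection, the smallest singular direction's
sign is flipped; reflections are numerical artefacts, not physical
motion. Note that a single triangle, being planar, is achiral in 3D —
a mirrored triangle is reached exactly by a proper 180° flip — which
is why the solver's reflection guard matters for robustness rather
than for triangle data specifically.

Triangles whose area is at or below 1e-6 mm² are rejected as errors
rather than warnings: landmark triples on teeth and ramus are never
collinear in valid data, so degeneracy indicates unusable input.

## The anatomical frame and the six clinical quantities

The natural-head-position frame is built from the reference
landmarks: the up/down axis is the unit normal of the Frankfort plane,
fit by least squares through both porions and *all available* orbitale
points (the convention does not specify a side, so using both,
when present, is the symmetric choice), oriented cranially (toward
nasion); the left/right axis runs from left to right porion, projected
into the plane; anterior/posterior completes the right-handed set
toward nasion; the origin is sella. Orthonormality is enforced by
Gram–Schmidt, and degenerate configurations (coincident porions,
collinear plane landmarks, an anterior axis pointing away from nasion)
raise errors naming the offending landmarks.

A segment transform is decomposed into:

* `d_ap`, `d_lr`, `d_ud` (mm): displacement of a reference point,
  projected on the frame axes. Signs: anterior, patient's right, and
  cranial are positive. The rotation part of a rigid transform is
  independent of the reference point, but the translation is not; the
  package reports the displacement of the *source triangle centroid*,
  which is the natural segment-attached point (the pipeline passes it
  automatically; `decompose_transform()` defaults to the frame origin
  for bare transforms).
* pitch, roll, yaw (degrees): right-handed rotations about the LR, AP
  and UD axes, factored by the fixed intrinsic sequence yaw → roll →
  pitch. Positive angles appear anti-clockwise viewed from the
  patient's right, from anterior, and from above, respectively; a
  positive pitch tips the incisal edge cranially/anteriorly.

Two conventions here deserve emphasis because the reporting tradition
is ambiguous:

* **Cranial-positive `d_ud`.** Verbal descriptions of the up/down sign
  are frequently self-contradictory in clinical tables; this package
  fixes cranial displacement as positive and documents it in every
  report header.
* **Autorotation and flare** of the proximal segments are not
  standardized terms. They are defined here as the pitch-like
  (about LR) and yaw-like (about UD) components of the proximal
  segment's preop→postop rotation, under the same Euler sequence and
  signs as the planned segments. Proximal segments are not planned in
  3D, so no accuracy report exists for them.

### Euler-sequence sensitivity

Any fixed factorization order is a convention. The discrepancy between
orders is second-order in the angles: re-extracting the angles of the
same rotation under the reversed (pitch → roll → yaw) order differs
from the nominal angles by up to about 0.16° when all three angles
reach 3°, and by less than 0.02° at 1° (both bounds are
regression-tested). At the magnitudes relevant for surgical accuracy
(a few degrees) the order choice therefore cannot change a clinical
reading, but the difference is *not* below 0.01° once angles reach
2–3°; claims of order-independence at that precision hold only below
roughly 0.7° per angle. Decomposition near the factorization's
singularity (roll within machine tolerance of ±90°, unreachable for
anatomical data) raises an explicit gimbal-lock error instead of
silently wrapping.

## Registration stand-ins

The planned→postop transform of a segment can also be recovered from
images or surfaces, mirroring the clinical workflow (voxel-based
matching for maxilla and distal segment, surface-based matching for
the proximal segments, whose metal-artefact-affected intensity data is
less reliable).

* **Volume registration**: rigid, multi-resolution (block-mean
  downsampling by 4/2/1), maximizing normalized cross-correlation
  (mean-squared difference of z-scored intensities selectable) with
  trilinear interpolation. NCC is the default because the synthetic
  phantoms are mono-modal, and it is fully deterministic. The
  optimizer is Nelder–Mead with a fixed iteration cap per level
  (400/300/300), a restart per level, and a deterministic grid search
  over ±6 mm translations at the coarsest level to establish capture
  range. An optional mask restricts the metric to a subvolume
  unaffected by surgery (the cranial-base region in the phantom); mask
  downsampling is inclusive (a coarse block counts if any fine voxel
  is masked). Registration with no usable overlap raises an error.
* **Surface registration**: point-to-point iterative closest point
  with 10% worst-pair trimming (robust to partial surfaces such as
  incompletely segmented condyles), centroid pre-alignment when no
  initialization is given, Kabsch updates, and convergence when the
  rmsd change falls below 1e-6 mm or after 200 iterations.

Both return proper rigid transforms by construction. The accuracy
property enforced in the tests is ground-truth recovery within 0.2 mm
translation — half of the 0.4 mm default voxel size — and 0.5°
rotation on the synthetic phantom; the implementation typically
achieves one to two orders of magnitude better on these inputs.

## Observer-reliability statistics

A measurement grid indexes movement components by (patient, session,
component), with sessions such as two analyses by one observer four
weeks apart (intra-observer) or analyses by two observers
(inter-observer).

* **Observer variation** between two sessions is the mean over
  patients of the absolute component difference. Its 95% CI is a
  percentile bootstrap over patients (default 10,000 resamples, seeded):
  with ten patients and no distributional knowledge of the
  differences, the bootstrap is the assumption-light choice.
* **ICC** is the two-way random-effects, absolute-agreement,
  single-measures form, ICC(2,1), computed from the ANOVA mean
  squares, with the F-distribution (McGraw–Wong) 95% CI. Absolute
  agreement is the appropriate form because sessions measure the same
  physical quantity and a systematic offset between observers is real
  disagreement, which consistency-type ICCs would hide.
* Missing cells are refused — no imputation in validation statistics.
  Zero between-patient variance makes the ICC undefined and raises an
  explicit error.

## What the synthetic generator emulates — and what it does not

`generate_phantom()` produces, deterministically per seed:

* a skull-like landmark constellation at anatomical scale (canonical
  natural head position, bilateral symmetry perturbed by 0.5 mm
  jitter), well-conditioned for frame construction, with segment
  triangle areas far above the degeneracy threshold;
* one irregular blob mesh per segment (UV-sphere with angular radius
  modulation, so surface registration has a unique optimum);
* a desk-scale textured intensity volume (default 64³ voxels at
  0.4 mm; the test suite uses 40³–48³) centred on the jaw region,
  containing distinct cranial-base / maxilla / mandible / proximal
  structures with smooth (≈0.5 mm) edges and a low-amplitude cosine
  texture that conditions rotation recovery, plus the cranial-base
  mask.

`simulate_surgery()` applies per-segment planning transforms, then an
execution-error transform drawn in anatomical-frame components
(rotations about the planned triangle centroid, so translation and
rotation errors remain interpretable; a rotation centre must be fixed
by convention because none is standardized). Default error-model
parameters were calibrated once to the dispersion typical of published
ten-patient wafer-transfer cohorts: translation means (−0.46, 0.29,
−0.45) mm and SDs (1.8, 0.7, 2.2) mm for (AP, LR, UD); rotation means
(1.37, −0.54, 0.51)° and SDs (3.0, 1.1, 1.3)° for (pitch, roll, yaw);
landmark identification noise 0.1 mm per coordinate.

`simulate_observer_sessions()` re-identifies the preoperative
landmarks per session (independent 0.1 mm noise by default) and
carries them through the transfer chain, then perturbs the true
planned→postop transform with a per-session *alignment noise*
(defaults: 0.06/0.03/0.12 mm and 0.35/0.12/0.05° SDs). This mirrors
the workflow's error structure: identification noise largely cancels
because landmarks are placed once and transferred, and the dominant
observer-dependent variation is the sub-voxel alignment error of the
registration step itself. An earlier design that re-identified the
postoperative triangle independently per session was discarded as
unfaithful to that workflow (it also inflates pitch noise specifically,
because the dental triangles are nearly flat cranio-caudally). The
alignment-noise defaults are of the magnitude reported for voxel-based
matching at 0.4 mm voxels, slightly conservative.

Not emulated: CT physics (beam hardening, streak artefacts from
orthodontic appliances), occlusal surfaces, soft tissue, genioplasty
segments, and full-resolution fields of view. Passing tests on the
phantom therefore demonstrate the correctness of the *analysis
machinery* under a realistic error structure, not the clinical
performance of any particular registration software on real CBCT.

## Reporting conventions

Tables round half away from zero to 2 decimals (1.035 prints as 1.04;
banker's rounding would print 1.03), computing at full precision
internally. Directional counts ("n of 10 positioned more posteriorly
than planned") count strictly negative components; zeros count as
neither. Decimal commas in input files are normalized to dots with a
warning, since clinical tables mix both conventions. Reports embed the
package version, analysis mode, seed and a configuration hash, and are
byte-identical across reruns on identical inputs.

The bundled ten-patient example cohorts (`inst/extdata/`) illustrate
one caveat of published summary rows: two of their printed summary
cells (the mandibular left/right mean/absolute-mean and the mandibular
up/down mean) are inconsistent with their own per-patient columns —
most likely computed from full-precision values before rounding — and
are therefore excluded from the package's exact-reproduction checks;
the recomputed values are reported instead.

## Problem sizes and runtime choices

The test suite exercises 1000-transform Procrustes/decomposition
recovery, 40³–48³-voxel registrations, ~260-vertex ICP, ten-patient
synthetic cohorts and three-session observer grids; the full suite
runs in a few minutes on one CPU. These sizes were chosen as the
smallest that exercise every code path at meaningful conditioning,
and the vignette's statements about accuracy are exactly those the
tests compute.

## Known limitations

* The registration module is a desk-scale stand-in: equivalence to any
  commercial voxel-based-matching implementation is not claimed, only
  the half-voxel recovery property on synthetic data.
* ICC confidence intervals rely on balanced complete grids; unbalanced
  designs are rejected rather than approximated.
* The Euler-sequence and autorotation/flare axis assignments are
  package conventions (documented above); comparisons with tools using
  other conventions must convert explicitly.
* Translation components of a movement report depend on the chosen
  reference point (triangle centroid here); tools reporting, e.g.,
  incisal-point displacement will differ for rotated segments.
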