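# gnathometry

Quantifying how accurately a 3D virtual orthognathic plan was executed
in bimaxillary surgery (Le Fort I osteotomy of the maxilla plus
bilateral sagittal split osteotomy of the mandible).

## The problem

After bimaxillary surgery, the clinician wants to know, per
osteotomized segment, how far the achieved position deviates from the
3D virtual plan. Conventional cephalometric comparisons require the
same landmarks to be identified in every dataset, so landmark
identification errors (0.02–2.5 mm per landmark) accumulate and can
swamp the clinically relevant 0.5 mm margin. The approach implemented
here eliminates repeated identification: three landmarks are placed
*once* per segment on the preoperative model and form a **virtual
triangle** that encodes the segment's position and orientation. The
triangle is carried along by the planning transform to the planned
position, and then by rigid image/surface registration to the
postoperative position, so the same physical triple of points is
compared across states.

## Method

For a segment with triangle vertices `X` (one state) and `Y`
(another state, same fixed vertex order), the segment motion is the
proper rigid transform minimizing the least-squares vertex mismatch
(rigid Procrustes / Kabsch):

    (R, t) = argmin Σᵢ ‖R xᵢ + t − yᵢ‖²,   R ∈ SO(3)

solved in closed form by SVD of the cross-covariance, with the sign of
the smallest singular direction corrected so that det(R) = +1 (no
reflection, no scaling). Two motions are reported per planned segment:

* **surgical displacement** — preoperative → postoperative,
* **surgical accuracy** — planned → postoperative (all-zero for a
  perfectly executed plan).

Each motion is decomposed in the **natural-head-position anatomical
frame** built from cephalometric landmarks (up/down axis = normal of
the Frankfort plane through both porions and the orbitale points,
left/right axis from left to right porion projected into that plane,
anterior/posterior axis completing the right-handed set toward nasion,
origin at sella) into the six clinical quantities: translations
`d_AP` (anterior +), `d_LR` (patient's right +), `d_UD` (cranial +) of
the triangle centroid, and rotations pitch / roll / yaw (right-handed
about the LR / AP / UD axes; anti-clockwise positive in the standard
views), factored by the fixed intrinsic sequence yaw → roll → pitch.
The proximal (condyle-bearing) mandibular segments are not planned in
3D; for them only the preop → postop **autorotation** (pitch-like) and
**flare** (yaw-like) rotations are reported.

Around this core the package provides:

* desk-scale rigid **volume registration** (multi-resolution
  normalized cross-correlation, trilinear interpolation, deterministic
  Nelder–Mead with a coarse-level capture-range search) and rigid
  **surface registration** (trimmed point-to-point ICP) to recover the
  planned→postop transform from per-segment images or meshes;
* **cohort summaries** (signed mean, absolute mean, directional
  counts per component);
* **observer-reliability statistics**: mean absolute between-session
  variation with percentile-bootstrap 95% CIs, and ICC(2,1)
  (two-way random effects, absolute agreement, single measures) with
  F-distribution CIs;
* a deterministic **synthetic skull phantom** (landmark constellation,
  per-segment blob meshes, textured intensity volume with a
  cranial-base mask) plus simulated planned movements, execution
  errors and observer sessions, so the whole pipeline is testable
  without any CT data;
* delimited-text I/O for landmarks, planning transforms, grids and
  reports; NIfTI/MetaImage volumes; STL/PLY meshes; and a small CLI
  (`inst/cli/gnathometry.R` — subcommands `analyze`, `summarize`,
  `validate`, `simulate`).

## Worked example

Simulate one patient whose maxilla was planned 4 mm anteriorly but
executed with an error, then recover that error:

```r
library(gnathometry)

phantom <- generate_phantom(seed = 42)
frame   <- build_frame(phantom$landmarks)
plan    <- list(maxilla = rigid_transform(diag(3), 4 * frame$axis_ap))
case    <- simulate_surgery(phantom, plan,
                            error_model(landmark_noise_sd = 0),
                            seed = 42, segments = "maxilla")
compute_case(case)
#> Case synthetic_42
#>  accuracy (planned -> postop):
#>   maxilla: AP +2.01  LR -0.11  UD +0.35 mm | pitch +3.27  roll -0.10  yaw +0.37 deg
#>  displacement (preop -> postop):
#>   maxilla: AP +6.01  LR -0.11  UD +0.35 mm | pitch +3.27  roll -0.10  yaw +0.37 deg
```

The accuracy report equals the injected execution error exactly (the
segment ended 2.01 mm anterior and 3.27° pitched relative to its
plan), and displacement = plan (4 mm advancement) + error (6.01 mm
total advancement).

Summarizing the bundled ten-patient maxillary accuracy cohort
(`inst/extdata/cohort_maxilla_accuracy.tsv`):

```r
s <- summarize_cohort(df)   # df = the bundled per-patient table
#>   component  mean abs_mean n_negative n_positive  n
#> 1      d_ap -0.46     1.41          7          3 10
#> 2      d_lr  0.29     0.49          4          6 10
#> 3      d_ud -0.45     1.85          6          4 10
#> 4     pitch  1.37     2.72          3          7 10
#> 5      roll -0.54     1.04          7          3 10
#> 6       yaw  0.51     0.97          4          5 10
```

Reading: on average the maxilla ended 0.46 mm posterior to its plan
(7 of 10 patients posterior), vertical control was weakest among the
translations (1.85 mm absolute mean), and pitch was the largest
rotational discrepancy (2.72° absolute mean).

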