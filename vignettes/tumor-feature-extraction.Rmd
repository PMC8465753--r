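---
title: "Atlas-based tumor feature extraction and segmentation validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based tumor feature extraction and segmentation validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomask)
```

## Scope and rationale

Glioblastoma surgery planning and audit benefit from a *standardized*
description of a tumor: where it sits, how big it is, whether it is
multifocal, how much of it is expected to be surgically removable, and
which cortical and subcortical structures it involves. `gliomask`
computes such a profile from a binary tumor segmentation mask that has
already been registered to a common reference space (nominally the
symmetric ICBM2009a template), together with an atlas bundle of
reference-space volumes. It also implements the validation machinery
used to benchmark automatic segmentation models against manual ground
truths: pixelwise overlap/boundary metrics, object-level detection
metrics, pooled cross-validation estimates, and inter-rater consensus
masks. Image registration itself, model training and inference are out
of scope: the package consumes their products.

## The feature record

From a refined reference-space mask, 233 named parameters are computed
in six groups:

* **Volume (2)** — voxel count times the voxel volume (the product of
  the three spacing values, mm^3), in mL, reported in the native
  patient space and in the reference space. All other features are
  reference-space quantities.
* **Laterality (3)** — the percentage of tumor voxels in each
  hemisphere (they sum to 100 by construction) and a midline-crossing
  flag that is true as soon as at least one voxel lies strictly on each
  side. The hemisphere mask is a total partition at the world plane
  x = 0; a voxel centre exactly on the plane counts as left. This is a
  measure-zero convention on real lattices: it can only matter when the
  lattice has a column of voxels exactly on the midline.
* **Multifocality (3)** — stand-alone foci are connected components of
  the mask. The biggest focus is the one of maximal volume (per-focus
  equivalent-sphere diameters, d = 2(3V/4*pi)^(1/3), are carried as
  auxiliary output only). A focus counts as an independent satellite
  only if its minimum surface distance from the biggest focus is at
  least 5.0 mm; closer fragments are not counted and do not contribute
  to the reported distance, but they remain part of the tumor for
  volume, laterality and overlap purposes (they are ignored for
  counting, not merged). Reported are the multifocality flag, the
  number of independent foci, and the largest of the satellites'
  minimum distances; a unifocal tumor reports the sentinel -1.0 mm.
* **Resectability (2)** — a population-derived resection-probability
  heat map exists per hemisphere; the map of the hemisphere holding the
  larger share of the tumor is used (an exact 50/50 tie goes to the
  left map). The expected resectable volume is the sum of heat-map
  probabilities over tumor voxels times the voxel volume; the expected
  residual volume is tumor volume minus resectable volume, and the
  resectability index is the resectable fraction in [0, 1]. By
  construction residual + resectable = tumor volume to numerical
  precision. Heat-map normalization is treated as a property of the
  data, not of the code.
* **Cortical location profile (87)** — for each structure of four
  parcellations (a 15-structure structural atlas, the 48-structure
  Harvard-Oxford cortical atlas, and 7- and 17-network functional
  parcellations), the percentage of tumor volume overlapping the
  structure. Within one parcellation structures are disjoint, so each
  atlas's overlaps sum to at most 100.
* **Subcortical location profile (2 x 68)** — the subcortical atlas is
  probabilistic; each of its 68 structures (40 unique names once
  left/right designations are stripped) is binarized at probability
  >= 0.5 (inclusive, so exactly-0.5 voxels are inside). Reported per
  structure: the overlap percentage, and a distance that is 0.0
  whenever the overlap is positive and otherwise the *directed*
  95th-percentile distance from the tumor's boundary voxels to the
  structure mask — a robust "how far is the tumor from this tract"
  summary that ignores the farthest 5% of boundary voxels. The
  direction is tumor-to-structure deliberately: the symmetric form
  would be dominated by the structure's own extent. Structures that
  are empty after thresholding report the sentinel -1.0.

An empty refined mask produces an explicit "no tumor" record
(`is_empty_record()`), never a row of silent zeros.

### Mask refinement

Automatic segmentations carry speckle and thin gaps. Refinement applies
a binary closing with a spherical structuring element of radius 2
*voxels* (the ball of index offsets with Euclidean norm <= 2; the
reference space is approximately 1 mm isotropic, so voxel and mm radii
coincide) with two iterations — two dilation passes followed by two
erosion passes — and then removes connected components smaller than
0.1 mL. The volume cut is strict ("smaller than"), so a component of
exactly 0.1 mL survives. Closing is computed on a lattice zero-padded
by radius x iterations and cropped back, which makes the operator
extensive (it never deletes foreground, including at the volume
border); an unpadded zero-boundary erosion would nibble border-touching
tumors, which is an artifact, not a feature. Note that closing can
merge foci that approach within roughly twice the dilation depth and
can add boundary voxels; it is intended for noisy model output, and
callers with already-clean masks can skip it.

### Conventions

Three conventions the source material leaves open are fixed once,
exposed as arguments, and used consistently:

* **Connectivity** is 26-neighbourhood for all tumor component
  analyses, the common choice for 3D lesions; 6 and 18 are available.
* **Distances** are Euclidean in world millimetres between voxel
  centres, through the geometry's voxel-to-world affine, so anisotropic
  spacings are handled exactly.
* **HD95** is the symmetric max of the two directed 95th percentiles of
  surface-voxel nearest-neighbour distances (surface = foreground voxel
  with a background 6-neighbour); percentiles use R's default (type 7)
  linear interpolation, matching the common Python implementations.

## Segmentation validation

* **Pixelwise**: the probability map is binarized at ten equally spaced
  thresholds. The bin centres 0.05, 0.15, ..., 0.95 are used rather
  than including 0 and 1, where binarization degenerates to
  all-foreground or all-background; the sweep is configurable. Dice is
  2|A n B|/(|A|+|B|), with the empty-vs-empty case defined as 1
  (agreement on absence) and empty-vs-nonempty as 0. HD95 is undefined
  for an empty operand and is reported as `NA`; cohort aggregation
  (`aggregate_hd95`) skips undefined cases and reports how many were
  skipped.
* **Patientwise**: components under 50 voxels are discarded on both
  sides, ground-truth tumors are paired one-to-one to predicted
  components greedily by descending intersection size (ties broken by
  label order, which is raster order and hence deterministic), and a
  ground-truth tumor is a true positive when its pairing Dice is at
  least 0.25. Unpaired predicted components are false positives; FPPP
  is their count per patient. A paired-but-below-threshold component
  is a miss for the tumor but deliberately not also a false positive.
  Recall, precision and F1 follow; Dice-TP averages pairing Dice over
  detected tumors only. On single-tumor cases the protocol reduces to
  thresholding the whole-volume Dice. A many-to-one merge mode was
  considered and rejected as the default: one-to-one greedy is simpler
  to reason about and reproduces the single-tumor reduction exactly.
* **Pooled estimates**: per-fold means/SDs/sizes combine by
  size-weighted mean and by the pooled variance
  `(sum_i [(n_i - 1) s_i^2 + n_i (m_i - m)^2]) / (N - 1)`, which is
  algebraically the sample variance of the concatenated per-patient
  values — the tests verify this against brute-force concatenation.
* **Consensus**: a voxel enters the consensus ground truth when at
  least half of the raters annotated it — with eight raters, four
  suffice (the count comparison is `>= R/2`, not `> R/2`).

## The synthetic generator

Every stage is testable offline through seeded generators
(`generate_bundle`, `generate_phantom`); all output is a pure function
of the phantom specification and seed.

The bundle generator emulates the *structure* of a reference-space
atlas bundle: a hemisphere partition at x = 0; four disjoint box-tiled
parcellations with the canonical 15/48/7/17 structure counts; 68
subcortical probability fields (28 mirrored left/right pairs plus 12
midline structures, hence 40 base names) with linear radial profiles
p = max(0, 1 - d/r) and profile radii drawn from 5-9 mm, so the 0.5
threshold yields balls of radius r/2; and per-hemisphere heat maps that
decay linearly from each hemisphere's centroid, reaching about 0.1 at
the far edge. The default lattice is 48 x 56 x 48 voxels at 1 mm —
roughly quarter-scale relative to a full head volume, which keeps a
full pipeline run in the tens of milliseconds range while leaving room
for multi-focal phantoms; the same code accepts full-resolution
geometries.

The phantom generator voxelizes analytic spheres (a voxel is foreground
iff its centre is inside), derives a probability map with a linear
soft edge crossing 0.5 exactly on the analytic surface, and simulates
raters by perturbing each sphere's radius by a seeded uniform offset of
at most `rater_noise` voxels, giving the surface-restricted spread that
makes majority voting meaningful. Truth tables are recorded from the
voxelized lattice, not the analytic ideal, so pipeline-recovery tests
can demand exactness for counts and percentages rather than loose
tolerances. Foci that would touch after voxelization are rejected.

What the generator does **not** emulate: real anatomy (parcels are
boxes, tracts are balls), MRI intensities, registration error,
segmentation-model failure modes, or realistically irregular tumor
margins. Passing recovery tests therefore demonstrates that the
feature computation is correct on its defined inputs — not that any
upstream segmentation or registration is accurate on clinical data.
Cohort-level results reported for trained neural networks on clinical
MRI are correspondingly outside what this package can or does
reproduce; the validation machinery is provided so such studies can be
run when those data and models are available.

## Numerical choices and problem sizes

Tolerances in the test suite are either exact (voxel counting,
percentages, label partitions), 1e-6 (float round trips through 32-bit
NIfTI storage, resectability summation), or one voxel volume / one
voxel diagonal where voxelization quantizes an analytic quantity.
Brute-force oracle comparisons (flood fill, all-pairs surface
distances) run on randomly seeded lattices up to 12^3, where the
O(n^2) oracles are fast; the packaged kernels are exercised on the
same inputs and must agree exactly. Pipeline-recovery checks use 20
seeded phantoms on the 48 x 56 x 48 default geometry, one or two foci
each. Reports format numbers with two decimals; CSV output keeps full
double precision.

## Known limitations

* The feature record assumes the input mask is already in the bundle's
  geometry; only nearest-neighbour resampling is provided
  (`resample_to_geometry`), no registration.
* Structure *names* are data: the package validates counts (15/48/7/17
  cortical, 68/40 subcortical) but does not ship the published
  atlases, whose redistribution terms differ; a loader for the
  documented bundle directory layout is provided instead.
* HD95-based structure distances are reported for non-overlapping
  structures only; a plain minimum distance can be obtained with
  `min_surface_distance` if preferred.
* The greedy pairing in `patientwise_detection` is one-to-one; a
  fragmented prediction covering one tumor with several components
  credits only the best fragment.
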