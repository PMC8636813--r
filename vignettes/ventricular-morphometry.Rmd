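---
title: "Ventricular morphometry on labelled brain volumes: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular morphometry on labelled brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ventmorph)
library(dplyr)
```

## The problem

Normal pressure hydrocephalus (NPH) presents with enlarged cerebral
ventricles at normal CSF pressure, and the decision to shunt hinges on
whether a patient responds to trial CSF drainage. Radiological work-up
leans on linear indices read off a scan realigned to the
anterior-commissure/posterior-commissure (ACPC) axis: the classical 2d
measures — Evans index (EI), bicaudate index (BCI), callosal angle (CA) —
and the newer 3-directional measures — the z-Evans index and the
brain-per-ventricle ratio (BVR) at the AC and PC levels — plus voxel-count
ventricular volumetry as an independent correlate.

This package implements that measurement chain end to end for labelled 3D
volumes (codes: 0 background, 1 brain, 2 ventricle, 3 cranium shell), along
with the clinical scoring used around it (mFI-11 frailty, the MCID
drainage-responder rule) and the nonparametric statistical layer (Fisher
exact, Mann-Whitney, Wilcoxon signed rank, ICC) that builds the familiar
cohort comparison tables. Because patient imaging of this kind is not
publicly distributable, the package also ships two generators that stand in
for it: geometric phantoms with closed-form morphometry, and simulated
cohorts drawn from published group summary statistics.

## Index definitions and measurement conventions

All measurements operate in a canonical RAS-like ACPC frame: AC at the
origin, PC at `(0, -d, 0)`, midsagittal plane `x = 0`, +z superior.
[align_volume()] estimates the rigid map from three landmarks (AC, PC and a
midsagittal point) and resamples the label volume by nearest-neighbour
interpolation, which cannot invent labels.

* **EI** — maximal frontal-horn width over axial slices, divided by the
  maximal internal cranial width. The frontal horns are the ventricle
  voxels anterior to the AC (`y > 0`); the labelling carries no finer horn
  boundary.
* **BCI** — maximal ventricular width over lines between PC and AC on the
  ACPC axial slice, divided by the brain width along the chosen line. The
  caudate nuclei are not labelled, so the intercaudate line is approximated
  by the widest ventricular line in that band; lines within half a voxel of
  the AC are excluded because they abut the (wider) frontal-horn face.
* **CA** — angle between the two ventricular roof lines on the coronal
  slice at the PC, fitted per side over the roof's topmost voxels.
* **z-Evans** — maximal per-column vertical ventricular extent on the
  coronal slice at the AC, divided by the maximal per-column cranial
  vertical extent there. Per-column extents (not the slice bounding box)
  keep tilted horns from inflating the numerator.
* **BVR (AC/PC)** — ventricular height and the brain mantle directly above
  it, both read at the column where the ventricular height peaks (near-ties
  broken toward the midline); the ratio is brain over ventricle. The PC
  components are also reported in mm.
* **Volume** — exact voxel count times voxel volume, in cm³.

Three numerical conventions matter and are used everywhere:

1. **Extents are edge-to-edge**: `(max index - min index + 1) * spacing`,
   so a 38 mm box voxelized at 1 mm measures exactly 38 mm.
2. **Maximal searches are stabilised**: profiles of per-line extents pass
   through a 3-line running median before the maximum is taken (a median of
   three adjacent measured extents is itself a measured extent), and ties
   resolve toward the slice or column nearest the AC/midline. Without this,
   "max over many jagged lines" is biased upward by resampling noise.
3. **Coronal reads "at" the AC** use the first slab anterior to it — the
   geometry is one-sided at the AC boundary — while the PC level uses the
   nearest slab, the ventricular body being continuous across it.

Two reads get additional care because a single resampled slice is too noisy
for them:

* The **CA roof slope** is not a least-squares line. A 1 mm voxel staircase
  over a ~20 mm roof limits any straight-line fit to roughly 2-4 degrees of
  angle error, and a single staircase aliases when the true slope is near a
  simple rational. Instead the roof tops are pooled over a thin coronal
  slab (±3 voxels around the PC) and the slope is the value that minimizes
  the per-slab trimmed spread of the de-trended tops `z + s·x` — for the
  correct slope, one slab's de-trended tops collapse into a single
  quantization band. On 400 exact synthetic staircases this estimator's
  worst error was 1.8°, against 3.8° for least squares. The per-side fitted
  slopes are reported for audit.
* The **BVR apex** is the intersection at the midline of the two per-side
  roof-line fits (for a flat roof both fits return the plateau), clamped to
  within 1.5 voxels above the tallest observed roof voxel. Reading the apex
  from a single column center misses it by up to one voxel, and that error
  is amplified by the brain/ventricle ratio.

## The phantom generator

[phantom_spec()] describes a head-like test object directly in the ACPC
frame: a box or ellipsoid cranium interior filled with brain, a
bilaterally symmetric ventricular system, and a thin cranium shell.
The ventricle has a frontal-horn block (width, height and anterior reach
are parameters) and a body whose roof is a symmetric tent
`z = apex - s·|x|`: the tent slope `s` fixes the callosal angle at
`180 - 2·atan(s)` degrees, the apex height at PC is the BVR "Ventricle"
component, and the outer body width is the BCI numerator. Every measured
quantity is therefore an explicit parameter, and [analytic_truth()] returns
the exact continuous-geometry value of all six indices and the volume
before any voxelization.

```{r phantom}
ph <- make_phantom(phantom_spec())
glance(ph$truth)
aligned <- align_phantom(ph)
glance(measure_all(aligned))
```

Two geometric choices deserve explanation:

* The body spans the midline as a single tent rather than two prisms
  separated by a septum. With a gap, the roof peak and the tallest column
  sit at a vertical face, and any read of them from a voxel grid is
  sub-voxel ill-posed; with the tent, the apex is interior and the callosal
  roof fit sees the full half-width of columns. Only the measured extents
  need to be anatomically controlled, not the topology.
* The body roof rises gently toward the front (`roof_tilt`, default 0.25
  dz/dy, apex height at the PC level unchanged). A perfectly prismatic roof
  would make every coronal slab carry the identical staircase, which
  re-introduces the aliasing the slab-pooled CA fit is designed to break.
  Anatomically, the ventricular roof does rise toward the frontal horns.

Phantoms can be exported at an arbitrary rigid pose (`pose =`), which is
how the ACPC alignment stage is exercised: a posed phantom, aligned via its
own landmarks, must reproduce the unposed measurements. The voxel grid is
snapped to a half-spacing lattice so that identity-pose phantoms with
integer dimensions voxelize exactly.

**Tolerances.** At spacing `h`, each ratio index is recovered within
`2h / denominator` of its analytic value, the callosal angle within 2°, and
the volume within 5%; the same bounds hold between posed-aligned and
unposed measurements. These are verified over 20 seeded random phantoms
(box crania, tent roofs with slopes 0.35-0.85, ventricles 44-56 mm wide) in
the test suite. Ellipsoid ventricles are the exception for BVR: their
continuum crown is tangent to the voxel grid, so recovery there is checked
against a brute-force voxel oracle rather than the continuum value.

## The cohort simulator

[default_paper_params()] loads a versioned registry
(`extdata/cohort-defaults.json`) of group-level means and SDs for the six
indices — NPH / Alzheimer's disease (AD) / healthy control (HC) baselines,
Classic/Complex NPH subtypes, and drainage Responder / Non-Responder groups
pre and post external lumbar drainage, including the BVR-at-PC
brain/ventricle components and ventricular volume — together with
comorbidity prevalences (hypertension 81%, impaired sensorium 61.9%, ...)
and group sizes (21/21/21; responders 9 of 21). One registered SD (the
pre-drainage ventricular BVR component in responders, 0.490) is internally
inconsistent with its neighbours; it is carried verbatim and flagged in
`params$flags`.

[simulate_cohort()] draws per-subject measures from multivariate normals at
those parameters, truncated to each measure's valid range (ratios to (0,1),
angles to (0,180), positive measures to (0, ∞)) by resampling rather than
clipping, which keeps sample means at the nominal values when truncation is
mild; if truncation would reject more than half the draws for any measure,
the parameters are rejected as inconsistent. Correlation structure is not
reported in group summaries, so two knobs cover it: `rho_between = 0.5`
between measures within a subject and `rho_within = 0.9` between the pre
and post values of a measure (the pre/post covariance is the Kronecker
product of the two equicorrelation structures). Comorbidity items are
independent Bernoulli draws at the registered prevalences — no published
covariance exists — and the outcome-change scores attached to the pre/post
design are generator plumbing: drawn from plausible distributions and
constrained to agree with the subject's responder label, so the MCID
classifier can be exercised end to end.

```{r cohort}
cohort <- simulate_cohort(default_paper_params(), "baseline", seed = 1)
tab <- build_comparison_table(
  cohort, c("ei", "bci", "ca_deg", "z_evans", "bvr_ac", "bvr_pc"),
  group = "group"
)
tab |> filter(group2 == "AD") |> select(measure, summary1, summary2, p_value)
```

What passing simulations show — and what they do not: the cohorts are
faithful to the published group-level first and second moments and
prevalences, but they carry none of the things real MRI cohorts do
(non-normal shapes, measure-specific correlation, scanner effects,
rater variability), so agreement here validates the statistical machinery,
not claims about new patient data. Likewise the phantoms validate the
geometry of the measurement code, not segmentation quality: clinical-grade
ventricle segmentation is explicitly out of scope, and
[segment_by_threshold()] (intensity threshold + 26-connectivity from a
seed) exists only to exercise the intensity-to-mask-to-volume path on
phantom images.

## Clinical scoring and statistics

[mfi11_score()] counts the 11 binary comorbidity items and stratifies at
the conventional cut (0-2 vs ≥3); missing items are an error, never
imputed. Published item tables often list a combined cerebrovascular row;
the canonical 11-item instrument is implemented, with "CVA with deficit"
defaulting to absent when only the combined item is known.
[classify_responder()] applies the MCID rule: at least 10% improvement in
any observed inpatient domain (gait, balance, cognition) **and** at least
20% reported functional improvement, both bounds inclusive.

The test layer is two-tailed throughout with significance at 0.05 and no
multiple-testing correction (the comparison-table output carries the test
count so users can apply their own):

* [fisher_exact_2x2()] enumerates the hypergeometric table probabilities
  directly and sums those no more likely than the observed table (1e-12
  relative tolerance for likelihood ties) — the convention that yields
  p = 1.00 for balanced frailty stratifications.
* [mann_whitney()] and [wilcoxon_signed_rank()] use exact distributions for
  small tie-free samples (pooled n ≤ 20, resp. ≤ 25 non-zero differences —
  both configurable) and the normal approximation with tie and continuity
  corrections otherwise. Zero differences are dropped by default; the Pratt
  variant is available. Both are cross-checked against brute-force
  enumeration in the test suite.
* [icc_single()] computes ICC(2,1) and ICC(3,1) from the two-way ANOVA mean
  squares; which variant produced any given published repeatability figure
  is usually unstated, so both are exposed.

## Reproducible runs

[run_pipeline()] ties the stages into one deterministic workflow — phantoms
written and re-read as NIfTI + landmark JSON, aligned, measured; cohorts
simulated, scored and classified; comparison tables and a
responder-by-frailty Fisher contrast written as CSV — with the
configuration hash and seed recorded in `run_log.json`. Identical
configurations produce byte-identical tables.

Problem sizes used by the shipped validation: 20 random phantoms (~3.5M
voxels each at 1 mm) for recovery, 5 for pose invariance, 500 replicates
per measure for the group-separation checks, and 2000 replicates for the
null calibration of the rank tests; these sizes give stable results while
keeping a full run in a few minutes on one core.

## Known limitations

* Landmarks are inputs; there is no automatic AC/PC detection.
* The affine model is rigid + axis-aligned voxel grids; no nonrigid
  registration, no skull stripping.
* The BCI uses the widest ventricular line between PC and AC as an
  intercaudate surrogate; with caudate labels available one would do
  better.
* Whether published EI denominators used the inner skull table or the brain
  width is ambiguous; the cranium-interior extent (brain + ventricle) is
  used here.
* The simulator reproduces first and second moments only, and the
  generator's correlation knobs are assumptions, not estimates.
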