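# ventmorph

Ventricular morphometry and CSF-responsiveness analysis for normal
pressure hydrocephalus (NPH), for neuroimaging researchers who work with
labelled brain volumes and cohort tables.

NPH is diagnosed and managed around a small set of linear indices read off
an MRI realigned to the anterior/posterior-commissure (ACPC) axis.
`ventmorph` implements the full measurement chain on labelled 3D volumes
(0 background, 1 brain, 2 ventricle, 3 cranium shell):

- **ACPC alignment**: rigid realignment from AC/PC/midsagittal landmarks,
  nearest-neighbour label resampling.
- **2d indices**: Evans index `EI = max frontal-horn width / max internal
  cranial width` (axial); bicaudate index `BCI = max intercaudate
  ventricular width / brain width on the same line`; callosal angle `CA`,
  the angle between the ventricular roof lines on the coronal slice at
  the PC.
- **3-directional indices**: z-Evans index `zEI = max vertical frontal-horn
  extent / max cranial vertical extent` on the AC coronal slice;
  brain-per-ventricle ratio `BVR = brain mantle above the ventricle /
  ventricular height` at the AC and PC levels.
- **Volumetry**: exact voxel-count ventricular volume (cm³), plus a simple
  threshold + 26-connectivity segmenter for phantom intensity images.
- **Clinical scoring**: the 11-item modified Frailty Index (mFI-11) with
  the 0–2 / ≥3 stratification, and the MCID drainage-responder rule
  (≥10% inpatient-domain improvement AND ≥20% reported functional
  improvement).
- **Statistics**: two-sided Fisher exact (sum of no-more-likely tables),
  Mann-Whitney U and Wilcoxon signed rank (exact for small tie-free
  samples), ICC(2,1)/ICC(3,1), and a comparison-table builder in the
  familiar cohort-table layout.
- **Generators**: geometric head phantoms with closed-form values of all
  six indices and the volume (`phantom_spec()`, `analytic_truth()`), and
  cohort simulation from registered group means/SDs and prevalences
  (`default_paper_params()`, `simulate_cohort()`).

Everything tabular is tidyverse-native: cohort simulators and table
builders return tibbles, fitted/measured objects have `tidy()`/`glance()`
methods, and result types have `autoplot()` methods.

## Worked example

Measure a phantom whose morphometry is known in closed form:

```r
library(ventmorph)
library(dplyr)

ph <- make_phantom(phantom_spec())   # head phantom in the ACPC frame
glance(ph$truth)                     # analytic ground truth
#>      ei   bci ca_deg z_evans bvr_ac bvr_pc ventricle_volume_cm3
#> 1 0.423 0.354   127.    0.35  0.476  0.824                 127.

aligned <- align_phantom(ph)         # landmark-based ACPC realignment
glance(measure_all(aligned))         # voxel-grid measurement
#>      ei   bci ca_deg z_evans bvr_ac bvr_pc bvr_pc_brain_mm bvr_pc_ventricle_mm
#> 1 0.431 0.354   127.    0.35  0.476  0.810            27.8                34.2
```

Each measured index sits within its voxelization tolerance
(`2·spacing/denominator`, 2° for the angle) of the analytic value: an EI of
0.431 vs 0.423 is a one-voxel difference across a 130 mm cranium. The
BVR-at-PC components (brain 27.8 mm over ventricle 34.2 mm) are the two
rulers a radiologist would draw on the PC coronal slice.

Simulate an NPH/AD/HC cohort at registered group parameters and build the
baseline comparison table:

```r
cohort <- simulate_cohort(default_paper_params(), "baseline", seed = 1)
tab <- build_comparison_table(
  cohort, c("ei", "bci", "ca_deg", "z_evans", "bvr_ac", "bvr_pc"),
  group = "group"
)
tab |> filter(group1 == "NPH", group2 == "AD") |>
  select(measure, summary1, summary2, p_value)
#>   measure summary1        summary2              p_value
#> 1 ei      0.362 ± 0.050   0.283 ± 0.033    0.00000137
#> 2 bci     0.273 ± 0.026   0.191 ± 0.035    0.0000000841
#> 3 ca_deg  52.415 ± 18.808 106.539 ± 16.924 0.000000192
#> 4 z_evans 0.452 ± 0.051   0.301 ± 0.035    0.0000000313
#> 5 bvr_ac  0.673 ± 0.151   1.413 ± 0.319    0.0000000361
#> 6 bvr_pc  0.816 ± 0.167   2.443 ± 1.014    0.00000754
```

Every NPH–AD contrast separates at p < 0.001 (Mann-Whitney, n = 21 per
group): ventricles larger (EI, BCI, zEI higher) and high-convexity tighter
(CA, BVR lower) in NPH, the pattern the indices were designed to capture.
A frailty stratification that splits 4/5 vs 5/7 across responders gives the
expected null Fisher result:

```r
fisher_exact_2x2(rbind(c(4, 5), c(5, 7)))
#>   statistic p_value method              n1
#> 1         4       1 fisher_exact_2x2    21
```

`run_pipeline(run_config(out_dir, seed = 1))` runs the whole chain —
phantom NIfTI export/import, alignment, measurement, cohort simulation,
scoring, tables — deterministically into an output directory with a
config-hash log.

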