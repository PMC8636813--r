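Package: ventmorph
Title: Ventricular Morphometry and CSF-Responsiveness Analysis for
    Normal Pressure Hydrocephalus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ventriculomegaly on labelled 3D brain
    volumes and relating it to cerebrospinal-fluid responsiveness in
    normal pressure hydrocephalus (NPH). Implements ACPC rigid
    realignment from anterior/posterior commissure landmarks,
    the classical 2d linear indices (Evans index, bicaudate index,
    callosal angle), the 3-directional indices (z-Evans index and
    brain-per-ventricle ratio at the AC and PC levels), and
    voxel-count ventricular volumetry. Includes generators for
    synthetic phantom volumes with analytically known morphometry and
    for simulated patient cohorts, modified Frailty Index (mFI-11)
    scoring, an MCID-based drainage-responder classifier, and the
    nonparametric group-comparison layer (Fisher exact, Mann-Whitney,
    Wilcoxon signed rank, intraclass correlation) used to build
    cohort comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
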