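Package: radnec
Title: Dose Equivalence and MRI Lesion Volumetry for Preclinical Radiation
    Necrosis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of radiation-necrosis studies in
    the rodent brain. Implements the linear-quadratic dose-equivalence
    calculus (biologically effective dose and single-fraction equivalent dose
    for arbitrary fractionation schemes), scan-geometry arithmetic and NIfTI
    volume handling for preclinical MRI, threshold-based lesion segmentation
    and volumetry using normal-cohort intensity statistics, longitudinal
    scheme-by-time ANOVA with Tukey post-hoc comparisons, and a seeded
    generator of synthetic phantom volumes and longitudinal cohorts with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    EBImage,
    igraph,
    car,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
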