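# radnec

Quantitative analysis of fractionation studies of radiation necrosis in the
rodent brain: linear-quadratic dose equivalence, threshold-based MRI lesion
volumetry, longitudinal scheme-by-time statistics, and a seeded synthetic
phantom/cohort generator for validating the whole chain against known ground
truth.

## The scientific problem

Fractionated radiotherapy is expected to spare late-responding tissue such
as brain, yet preclinical necrosis models are usually built with single
large fractions. To compare a fractionated regimen of *n* fractions of *d*
Gy against single-fraction exposures on a common biological scale, the
linear-quadratic (LQ) model provides the biologically effective dose

> BED = (n·d) · (1 + d / (α/β))

and the single-fraction equivalent dose, the non-negative root of
SFED · (1 + SFED/(α/β)) = BED:

> SFED = [−1 + √(1 + 4·BED/(α/β))] / (2/(α/β)),

where α/β (Gy) is the tissue sensitivity ratio — 2–3 Gy for late-responding
cerebrum, ~10 Gy for early-responding tissue/tumor. Lesion burden is then
tracked longitudinally on T2-weighted and post-contrast T1-weighted MRI: a
normal (control) cohort defines a reference intensity band (mean ± 2 SD of
brain voxels), voxels outside the band inside the brain mask count as lesion
(hyper- plus hypointense), and lesion volume is the flagged voxel count
times the voxel unit volume of the scan geometry (128×128 over 15×15 mm,
21 × 0.5 mm slices → ~0.117 mm in-plane, ~0.007 mm³ per voxel). Group
differences over scheme × week are tested by two-way ANOVA with Tukey
post-hoc comparisons; histology grades by one-way ANOVA with Tukey.

Because no animal MRI data are deposited for this design, the package ships
a seeded generator of phantom volumes (ellipsoidal Gaussian-noise brain,
inserted lesions of known voxel count) and longitudinal cohorts (saturating
lesion growth with onset at 2–3 weeks, subject-level frailty, arm censoring)
so that every stage can be validated against ground truth.

## Worked example

Dose equivalence for the four study regimens:

```r
library(radnec)
subset(schemeTable(), alpha_beta_Gy == 2)
#>   label  n d_Gy total_Gy alpha_beta_Gy  tissue_class BED_Gy  SFED_Gy
#> 1  5x20  5   20      100             2 late_cerebrum   1100 45.91482
#> 2 10x10 10   10      100             2 late_cerebrum    600 33.65545
#> 3  5x18  5   18       90             2 late_cerebrum    900 41.43819
#> 4  10x9 10    9       90             2 late_cerebrum    495 30.48015
```

Every fractionated scheme is "equivalent" to less than 50 Gy in a single
fraction at late-tissue α/β — the `doses` stage of `runAll()` writes the
full 12-row table (α/β ∈ {2, 3, 10}) as `doses.csv`.

Phantom → reference statistics → segmentation:

```r
ph  <- generatePhantom(phantomSpec(seed = 7,
         lesion = list(targetVolumeMm3 = 5, offsetSd = 5)))
ctl <- generatePhantom(phantomSpec(seed = 8))
stats <- computeReferenceStats(ctl$volume, ctl$brainMask)
stats
#> ReferenceStats (T2): mean 500.1, sd 25.03 over 60740 voxels from 1 subject(s)
thresholds(stats, k = 2)
#> IntensityThresholds: [450, 550.2] (k = 2)
segmentLesion(ph$volume, brainMask(ph$volume), thresholds(stats),
              minClusterVoxels = 27)
#> LesionResult 'phantom' (T2, week 0): 765 hyper + 37 hypo voxels = 5.507 mm^3
```

The inserted lesion rasterised to 5.05 mm³ of voxels; the measured 5.51 mm³
differs from truth by well under one boundary-voxel shell (the hypointense
voxels are noise fused to the lesion cluster — both intensity tails count as
lesion). `runAll(runConfig(design = ..., seed = ...))` chains dose table →
cohort simulation → volumetry (`measurements.csv`) → scheme × week ANOVA
with Tukey tables, reproducibly for a fixed seed.

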