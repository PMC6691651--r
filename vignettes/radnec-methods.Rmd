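---
title: "Methods: dose equivalence, threshold volumetry and cohort statistics in radnec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose equivalence, threshold volumetry and cohort statistics in radnec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radnec)
```

# Scope

`radnec` implements the quantitative chain of a preclinical fractionation
study of radiation necrosis: (1) linear-quadratic (LQ) dose equivalence,
(2) MRI scan-geometry arithmetic and NIfTI I/O, (3) threshold-based lesion
segmentation and volumetry, (4) longitudinal scheme-by-week statistics, and
(5) a seeded synthetic phantom/cohort generator that provides ground truth
for validating (2)–(4). This vignette documents the models, the parameters
that matter, the numerical decisions taken where the underlying experimental
procedure is under-specified, and what the validation can and cannot show.

# The linear-quadratic dose-equivalence model

For a scheme of $n$ fractions of $d$ Gy, the biologically effective dose is
the basic LQ form
$$\mathrm{BED} = (nd)\left(1 + \frac{d}{\alpha/\beta}\right),$$
with no time factor: repopulation and incomplete repair between fractions
are deliberately not modelled, so two schemes with equal BED are "equally
effective" only under the LQ assumptions of full inter-fraction repair and
no proliferation. The single-fraction equivalent dose solves the same
relation with $n = 1$, giving the non-negative root
$$\mathrm{SFED} = \frac{-1 + \sqrt{1 + 4\,\mathrm{BED}/(\alpha/\beta)}}
{2/(\alpha/\beta)}.$$
The negative root is always discarded; `sfedFromBed()` is total on
$\mathrm{BED} \ge 0$ and `sfedFromBed(0, ab) == 0`.

The $\alpha/\beta$ ratio is a tissue parameter in Gy: 2 and 3 Gy bracket the
conventional late-responding cerebrum value (treated as two separate grid
points, not a range), and 10 Gy represents early-responding tissue/tumor.
`schemeTable()` evaluates a scheme list against an $\alpha/\beta$ grid; its
defaults (5×20, 10×10, 5×18, 10×9 Gy × {2, 3, 10} Gy) are the four study
regimens and standard ratios, and reproduce the published dose-equivalence
table. Exact agreement is checked per cell at the precision the table
prints (BED to its printed decimals, SFED to 2), since the printed rounding
is heterogeneous.

# Scan geometry and volumetry units

A `ScanGeometry` fixes matrix size, in-plane field of view, slice count and
slice thickness; in-plane resolution is FOV/matrix per axis and the voxel
unit volume is the product of both in-plane resolutions and the slice
thickness. The default protocol (128×128 over 15×15 mm, 21 × 0.5 mm
slices) gives 0.1171875 mm and 0.0068665 mm³ — the values usually quoted
as ~0.117 mm and ~0.007 mm³. Volumes are arrays ordered (slice, row,
col); slice 0 is the first array plane, a pure convention since no
computation here depends on anatomical orientation. NIfTI-1 is the only
file format; intensities round-trip bit-exactly, and an expected geometry
can be enforced at load time (header spacings to 1e-3 mm).

# Threshold segmentation

The segmentation follows the reference-band principle: normal tissue
defines what "normal intensity" is, and lesion is whatever falls outside.

1. **Reference statistics.** Brain-masked voxels of all control subjects of
   one modality are pooled, and their mean and $(n-1)$ SD computed
   (`computeReferenceStats()`). Pooling across the cohort (rather than
   per-mouse or contralateral-hemisphere statistics) is a deliberate
   reading of "normal mice" as a cohort; a zero pooled SD is rejected as
   degenerate rather than silently producing empty thresholds.
2. **Thresholds.** `thresholds()` puts both cut-offs $k$ SDs from the mean;
   $k = 2$ by default. Under purely Gaussian normal tissue this flags
   $2(1-\Phi(k)) \approx 4.55\%$ of normal voxels at $k=2$ — the
   irreducible false-positive floor of the method, which the test suite
   verifies by simulation.
3. **Brain mask.** The original analysis used an in-house semi-automatic
   program whose manual step is not described. `radnec` therefore makes
   the procedure fully deterministic: a global Otsu threshold on the
   intensity histogram, the largest 6-connected foreground component, and a
   morphological closing with a 3³ structuring element. A user-supplied
   mask (`method = "provided"`) replaces this entirely, which is the
   reproducible analogue of manual brain delineation. Closing is
   implemented as a 27-shift max/min filter because a true 3-D structuring
   element is needed (framewise 2-D morphology would leave through-plane
   staircase artefacts).
4. **Lesion.** Within the brain mask, voxels above the upper cut-off
   (hyper) and below the lower cut-off (hypo) are both lesion; T1 and T2
   are segmented independently against their own reference statistics and
   never fused. Volume is count × voxel volume, so reported volumes are
   always integer multiples of the unit volume. An optional
   `minClusterVoxels` filter (26-connectivity) removes small flagged
   clusters; the default is 0 (no filter), since the original method
   describes none.

Useful invariants, all tested: lesion volume is non-increasing in $k$;
shifting all intensities and the reference mean together leaves the mask
unchanged; a volume equal to the reference mean yields volume 0.

# Synthetic phantoms and cohorts

The generator emulates exactly the statistical structure the segmentation
assumes — nothing more. A phantom is an ellipsoidal "brain" of i.i.d.
$\mathcal N(\mu, \sigma)$ voxels on a constant background, with an optional
contiguous lesion (ellipsoid or block) whose voxels are offset by a stated
number of SDs. Defaults, chosen once and kept: T2 brain mean 500 / SD 25,
T1post mean 400 / SD 20 (MRI intensities are arbitrary units; the two
modalities differ so cross-modality threshold bugs surface), lesion offset
+5 SD (markedly hyperintense, as contrast-enhancing necrosis is against
normal brain), brain semi-axes giving a ~415 mm³ brain at the default
geometry — the scale of a mouse brain. Lesions are rasterised to a target
volume; the realised voxel count (the ground truth) is recorded and always
within one boundary-voxel shell of the target, the intrinsic resolution
limit of voxelised volumetry. Lesions default to a mid-hemisphere
position, reflecting single-hemisphere irradiation.

Cohorts add a longitudinal layer: expected lesion volume per arm follows a
saturating growth curve, zero before an onset week (default 3; 2 for the
most intense arm) and approaching a plateau exponentially; a per-subject
lognormal frailty (σ = 0.2) multiplies the curve to create between-animal
spread; additive Gaussian measurement noise (default SD 0.5 mm³) perturbs
each target, truncated at zero. Arms may carry a censor week after which
no records are emitted, emulating early sacrifice of the highest-dose
single-fraction arm at 2 weeks. Imaging defaults to weeks {1, 2, 3, 4, 6}.
Plateau volumes in `defaultCohortDesign()` (7–15 mm³, ordered by total
dose) are illustrative: they produce lesions of a plausible scale, but no
published volume trajectory is being reproduced, and none is claimed.
Histology grades are generated on an ordinal 0–3 scale (none / mild /
moderate / severe) by binning each subject's asymptotic lesion burden.

What the phantoms deliberately do *not* contain: anatomical texture,
partial-volume edges, bias fields, motion, registration error, or
correlated noise. Passing the recovery tests therefore shows the
*algorithmic* chain is correct and calibrated, not that the method is
robust to real-MRI artefacts.

All generation is a pure function of (design, seed): every random draw
comes from one seeded stream in a fixed order, and per-phantom seeds are
drawn up front, so identical inputs give bit-identical volumes and CSVs.

# Longitudinal statistics

`twoWayAnovaTukey()` fits lesion volume on scheme, week (both categorical)
and their interaction by fixed-effects least squares and reports Type III
sums of squares under sum-to-zero contrasts — the appropriate choice for
the unbalanced group sizes such cohorts have (2 to 25 animals per cell in
the motivating design), and the convention of the commercial packages used
in this field; on balanced designs it coincides with the classical
decomposition, which the tests exploit by checking F statistics against a
brute-force sums-of-squares oracle to 1e-9. Pairwise scheme comparisons at
each week use the Tukey–Kramer (harmonic-mean) adjustment via estimated
marginal means, which reduces to classic Tukey HSD when balanced. If
censoring empties scheme × week cells the interaction is inestimable; it
is then dropped automatically with a recorded note, and the additive model
is reported. Repeated scans of the same animal are treated as independent
observations — a face-value fixed-effects design; a mixed model would be
the natural extension but is out of scope. `oneWayAnovaTukey()` applies
ordinary one-way ANOVA + Tukey–Kramer to histology grades, treating the
ordinal grade as numeric.

Degenerate inputs fail loudly, never silently: fewer than two levels of
either factor, zero total variance, duplicate (subject, week, modality)
records, and groups with fewer than two observations are all errors naming
the offending structure.

# Pipeline and reproducibility

`runAll()` chains dose table → cohort simulation → reference statistics →
batch volumetry → statistics from a single `runConfig()` (or YAML file).
The resolved configuration is written next to the outputs and its MD5 hash
is embedded, with the package version, in a `#` comment header on every
CSV; rerunning an identical configuration and seed reproduces all CSVs
bit-identically. Stage failures abort with the stage name and leave
completed artifacts in place. The package is a library with a programmatic
surface; the pipeline stages are ordinary exported functions rather than a
shell executable.

# Problem sizes used in validation

The test suite keeps simulations at the smallest sizes that make each check
meaningful: full-geometry phantoms (21×128×128, ~60,000 brain voxels)
wherever a rate or a volume is being estimated (Gaussian false-positive
rate to within 3 binomial SEs; lesion recovery across 0.5–20 mm³ judged
against one boundary-voxel shell, with `minClusterVoxels = 27` — one 3³
block — suppressing isolated noise voxels in that benchmark); a reduced
48×48×10 geometry for cohort-level and pipeline tests, where only the
bookkeeping and determinism are at stake; and 1000 replicates of a balanced
3-scheme × 3-week × 4-replicate null design for the type-I error
calibration of the scheme factor, which must land in [0.035, 0.065] at
$\alpha = 0.05$.

# Known limitations

- The LQ equivalence carries no time factor; protracted schedules with
  incomplete repair between fractions are outside the model.
- "Semi-automatic" segmentation is rendered fully automatic; any manual
  lesion editing in the original workflow is not emulated, only the
  reproducible parts (thresholds, masks, counting) are.
- Reference statistics assume Gaussian normal-brain intensities; heavy
  tails would inflate the 4.55% false-positive floor.
- The fixed-effects ANOVA ignores within-animal correlation across weeks.
- Phantoms are geometric, not anatomical; validation demonstrates
  correctness of the computation, not robustness to acquisition artefacts.
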