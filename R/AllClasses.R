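#' @import methods
NULL

#' Scan geometry of a 3-D MRI acquisition
#'
#' Describes the in-plane matrix, field of view and slice stack of an MRI
#' acquisition, from which in-plane resolution and voxel unit volume are
#' derived. The default constructor arguments correspond to a typical
#' preclinical rodent-brain protocol: a 128 x 128 matrix over a 15 x 15 mm
#' field of view with 21 slices of 0.5 mm thickness, giving an in-plane
#' resolution of ~0.117 mm and a voxel unit volume of ~0.007 mm^3.
#'
#' @slot matrixRows,matrixCols integer, acquisition matrix size.
#' @slot fovMm numeric of length 2, in-plane field of view in mm
#'   (row extent, column extent).
#' @slot nSlices integer, number of slices.
#' @slot sliceThicknessMm numeric, slice thickness in mm.
#'
#' @seealso [inplaneResolution()], [voxelVolume()]
#' @export
setClass("ScanGeometry",
  representation(
    matrixRows = "integer",
    matrixCols = "integer",
    fovMm = "numeric",
    nSlices = "integer",
    sliceThicknessMm = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (length(object@matrixRows) != 1L || is.na(object@matrixRows) ||
      object@matrixRows < 1L)
    msg <- c(msg, "matrixRows must be a positive integer")
  if (length(object@matrixCols) != 1L || is.na(object@matrixCols) ||
      object@matrixCols < 1L)
    msg <- c(msg, "matrixCols must be a positive integer")
  if (length(object@fovMm) != 2L || any(!is.finite(object@fovMm)) ||
      any(object@fovMm <= 0))
    msg <- c(msg, "fovMm must be two strictly positive values (mm)")
  if (length(object@nSlices) != 1L || is.na(object@nSlices) ||
      object@nSlices < 1L)
    msg <- c(msg, "nSlices must be a positive integer")
  if (length(object@sliceThicknessMm) != 1L ||
      !is.finite(object@sliceThicknessMm) || object@sliceThicknessMm <= 0)
    msg <- c(msg, "sliceThicknessMm must be strictly positive (mm)")
  if (length(msg)) msg else TRUE
})

#' @param matrixRows,matrixCols acquisition matrix size (pixels).
#' @param fovMm in-plane field of view in mm; a length-2 numeric or a single
#'   value used for both axes.
#' @param nSlices number of slices.
#' @param sliceThicknessMm slice thickness in mm.
#' @return `ScanGeometry()` returns a `ScanGeometry` object.
#' @examples
#' geom <- ScanGeometry()
#' inplaneResolution(geom)
#' voxelVolume(geom)
#' @rdname ScanGeometry-class
#' @export
ScanGeometry <- function(matrixRows = 128L, matrixCols = 128L,
                         fovMm = c(15, 15), nSlices = 21L,
                         sliceThicknessMm = 0.5) {
  if (length(fovMm) == 1L) fovMm <- rep(as.numeric(fovMm), 2L)
  new("ScanGeometry",
      matrixRows = as.integer(matrixRows),
      matrixCols = as.integer(matrixCols),
      fovMm = as.numeric(fovMm),
      nSlices = as.integer(nSlices),
      sliceThicknessMm = as.numeric(sliceThicknessMm))
}

.MODALITIES <- c("T1post", "T2")

#' A 3-D MRI volume with scan geometry and acquisition metadata
#'
#' Holds a 3-D intensity grid ordered (slice, row, col) together with its
#' [ScanGeometry-class] and cohort metadata (subject, imaging modality,
#' weeks post-irradiation). Intensities are stored as doubles; integer
#' input is promoted losslessly.
#'
#' @slot intensities 3-D numeric array, dimension
#'   `(nSlices, matrixRows, matrixCols)`; all values finite.
#' @slot geometry a [ScanGeometry-class].
#' @slot modality `"T1post"` (post-contrast T1-weighted) or `"T2"`
#'   (T2-weighted).
#' @slot subjectId character subject identifier.
#' @slot week numeric, weeks post-irradiation (non-negative).
#'
#' @export
setClass("ImageVolume",
  representation(
    intensities = "array",
    geometry = "ScanGeometry",
    modality = "character",
    subjectId = "character",
    week = "numeric"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  g <- object@geometry
  expected <- c(g@nSlices, g@matrixRows, g@matrixCols)
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3-D array (slice, row, col)")
  else if (!identical(as.integer(dim(object@intensities)), expected))
    msg <- c(msg, sprintf(
      "intensity grid is %s but geometry implies %s",
      paste(dim(object@intensities), collapse = "x"),
      paste(expected, collapse = "x")))
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "all intensities must be finite")
  if (!(length(object@modality) == 1L && object@modality %in% .MODALITIES))
    msg <- c(msg, sprintf("modality must be one of: %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(object@week) != 1L || !is.finite(object@week) || object@week < 0)
    msg <- c(msg, "week must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @param intensities 3-D numeric array ordered (slice, row, col).
#' @param geometry a [ScanGeometry-class]; its dimensions must match
#'   `dim(intensities)`.
#' @param modality `"T1post"` or `"T2"`.
#' @param subjectId subject identifier.
#' @param week weeks post-irradiation.
#' @return `ImageVolume()` returns an `ImageVolume` object.
#' @rdname ImageVolume-class
#' @export
ImageVolume <- function(intensities, geometry, modality = "T2",
                        subjectId = "unknown", week = 0) {
  storage.mode(intensities) <- "double"
  new("ImageVolume", intensities = intensities, geometry = geometry,
      modality = modality, subjectId = as.character(subjectId),
      week = as.numeric(week))
}

#' A radiation fractionation scheme
#'
#' A regimen of `n` fractions of `d` Gy each, as used in the
#' linear-quadratic dose-equivalence calculus. The total physical dose is
#' `n * d` Gy.
#'
#' @slot n integer, number of fractions (>= 1).
#' @slot d numeric, dose per fraction in Gy (> 0).
#' @slot label short display label such as `"5x20"`.
#'
#' @seealso [bed()], [doseMetrics()], [parseSchemes()]
#' @export
setClass("FractionationScheme",
  representation(n = "integer", d = "numeric", label = "character")
)

setValidity("FractionationScheme", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "fraction count n must be a positive integer")
  if (length(object@d) != 1L || !is.finite(object@d) || object@d <= 0)
    msg <- c(msg, "dose per fraction d must be strictly positive (Gy)")
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' @param n number of fractions.
#' @param d dose per fraction (Gy).
#' @param label display label; defaults to `"<n>x<d>"`.
#' @return `fractionationScheme()` returns a `FractionationScheme`.
#' @examples
#' s <- fractionationScheme(5, 20)
#' totalDose(s)
#' bed(s, alphaBeta = 2)
#' @rdname FractionationScheme-class
#' @export
fractionationScheme <- function(n, d, label = sprintf("%dx%g", as.integer(n), d)) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("fraction count n must be a positive integer, got: ",
         deparse(substitute(n)), " = ", paste(n, collapse = ","))
  if (length(d) != 1L || !is.finite(d) || d <= 0)
    stop("dose per fraction d must be strictly positive (Gy), got d = ", d)
  new("FractionationScheme", n = as.integer(n), d = as.numeric(d),
      label = as.character(label))
}

#' Linear-quadratic dose metrics for one scheme at one alpha/beta ratio
#'
#' The biologically effective dose (BED) and single-fraction equivalent dose
#' (SFED) of a [FractionationScheme-class] at a given alpha/beta ratio. The
#' two are linked by the quadratic identity
#' `SFED * (1 + SFED / alphaBeta) == BED`, which the validity method enforces
#' to a relative tolerance of 1e-9; for a single-fraction scheme SFED equals
#' the physical dose, and for `n > 1` SFED is strictly below the total dose.
#'
#' @slot scheme the [FractionationScheme-class].
#' @slot alphaBeta numeric, alpha/beta ratio in Gy.
#' @slot bed numeric, biologically effective dose in Gy.
#' @slot sfed numeric, single-fraction equivalent dose in Gy.
#'
#' @export
setClass("DoseMetrics",
  representation(scheme = "FractionationScheme", alphaBeta = "numeric",
                 bed = "numeric", sfed = "numeric")
)

setValidity("DoseMetrics", function(object) {
  msg <- character()
  if (length(object@alphaBeta) != 1L || !is.finite(object@alphaBeta) ||
      object@alphaBeta <= 0)
    msg <- c(msg, "alphaBeta must be strictly positive (Gy)")
  if (object@bed < 0) msg <- c(msg, "bed must be non-negative")
  if (object@sfed < 0) msg <- c(msg, "sfed must be non-negative")
  if (!length(msg)) {
    lhs <- object@sfed * (1 + object@sfed / object@alphaBeta)
    if (abs(lhs - object@bed) > 1e-9 * max(1, abs(object@bed)))
      msg <- c(msg, "sfed does not satisfy the LQ quadratic identity for bed")
    total <- object@scheme@n * object@scheme@d
    if (object@scheme@n > 1L && object@sfed >= total)
      msg <- c(msg, "sfed must be below the total dose for n > 1")
    if (object@scheme@n == 1L &&
        abs(object@sfed - object@scheme@d) > 1e-9 * max(1, object@scheme@d))
      msg <- c(msg, "sfed must equal d for a single-fraction scheme")
  }
  if (length(msg)) msg else TRUE
})

#' Pooled intensity statistics of a normal (control) cohort
#'
#' The mean and standard deviation of brain-masked voxel intensities pooled
#' over all control volumes of one modality. These reference statistics
#' anchor the +/- k SD segmentation thresholds.
#'
#' @slot modality `"T1post"` or `"T2"`.
#' @slot mean,sd pooled intensity mean and (n-1) standard deviation;
#'   `sd` must be strictly positive.
#' @slot nVoxels integer, number of pooled voxels (>= 2).
#' @slot sourceSubjects subject identifiers that contributed voxels.
#'
#' @seealso [computeReferenceStats()], [thresholds()]
#' @export
setClass("ReferenceStats",
  representation(modality = "character", mean = "numeric", sd = "numeric",
                 nVoxels = "integer", sourceSubjects = "character")
)

setValidity("ReferenceStats", function(object) {
  msg <- character()
  if (!(length(object@modality) == 1L && object@modality %in% .MODALITIES))
    msg <- c(msg, "modality must be T1post or T2")
  if (!is.finite(object@mean)) msg <- c(msg, "mean must be finite")
  if (!is.finite(object@sd) || object@sd <= 0)
    msg <- c(msg, "sd must be strictly positive")
  if (is.na(object@nVoxels) || object@nVoxels < 2L)
    msg <- c(msg, "nVoxels must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Lower/upper intensity cut-offs derived from reference statistics
#'
#' Thresholds at `mean - k*sd` and `mean + k*sd`; voxels outside this band
#' are flagged as hypo-/hyperintense. The conventional choice is `k = 2`.
#'
#' @slot lower,upper intensity cut-offs, `lower < upper`.
#' @slot k positive SD multiplier.
#'
#' @seealso [thresholds()], [segmentLesion()]
#' @export
setClass("IntensityThresholds",
  representation(lower = "numeric", upper = "numeric", k = "numeric")
)

setValidity("IntensityThresholds", function(object) {
  msg <- character()
  if (!is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "k must be strictly positive")
  if (!is.finite(object@lower) || !is.finite(object@upper) ||
      object@lower >= object@upper)
    msg <- c(msg, "lower must be strictly below upper")
  if (length(msg)) msg else TRUE
})

#' Result of threshold-based lesion segmentation on one volume
#'
#' The lesion mask (union of hyper- and hypointense voxels inside the brain
#' mask), the hyper/hypo voxel counts, and the lesion volume obtained by
#' multiplying the flagged voxel count by the voxel unit volume.
#'
#' @slot mask 3-D logical array, the lesion mask.
#' @slot nHyper,nHypo integer counts of hyper-/hypointense flagged voxels.
#' @slot volumeMm3 lesion volume in mm^3, equal to
#'   `(nHyper + nHypo) * voxelVolumeMm3`.
#' @slot voxelVolumeMm3 voxel unit volume used for the conversion.
#' @slot thresholds the [IntensityThresholds-class] applied.
#' @slot modality,subjectId,week acquisition metadata carried through.
#'
#' @seealso [segmentLesion()]
#' @export
setClass("LesionResult",
  representation(mask = "array", nHyper = "integer", nHypo = "integer",
                 volumeMm3 = "numeric", voxelVolumeMm3 = "numeric",
                 thresholds = "IntensityThresholds", modality = "character",
                 subjectId = "character", week = "numeric")
)

setValidity("LesionResult", function(object) {
  msg <- character()
  nFlag <- object@nHyper + object@nHypo
  if (sum(object@mask) != nFlag)
    msg <- c(msg, "mask voxel count must equal nHyper + nHypo")
  if (abs(object@volumeMm3 - nFlag * object@voxelVolumeMm3) >
      1e-9 * max(1, object@volumeMm3))
    msg <- c(msg, "volumeMm3 must equal flagged count times voxel volume")
  if (length(msg)) msg else TRUE
})

#' ANOVA-plus-Tukey report
#'
#' The factor-level ANOVA table and the Tukey (Tukey--Kramer) adjusted
#' pairwise comparisons produced by [twoWayAnovaTukey()] or
#' [oneWayAnovaTukey()].
#'
#' @slot factors character, names of the model factors tested.
#' @slot anova data.frame with columns `term`, `df`, `sumsq`, `F`, `p`.
#' @slot pairwise data.frame of pairwise comparisons with columns `groupA`,
#'   `groupB`, optional `week`, `meanDiff`, `adjustedP`, `unadjustedP`.
#' @slot note character, diagnostic notes (e.g. a dropped interaction term).
#'
#' @export
setClass("AnovaTukeyReport",
  representation(factors = "character", anova = "data.frame",
                 pairwise = "data.frame", note = "character")
)

setValidity("AnovaTukeyReport", function(object) {
  p <- object@anova$p
  pr <- object@pairwise$adjustedP
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(p) || !ok(pr)) "all p-values must lie in [0, 1]" else TRUE
})
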