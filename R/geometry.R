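#' In-plane resolution of a scan geometry
#'
#' Field of view divided by matrix size, per in-plane axis. For a 128 x 128
#' matrix over 15 x 15 mm this is 0.1171875 mm (~0.117 mm) in each
#' direction.
#'
#' @param geometry a [ScanGeometry-class].
#' @return named numeric of length 2 (`row`, `col`), mm per pixel.
#' @rdname inplaneResolution
#' @export
setMethod("inplaneResolution", "ScanGeometry", function(geometry) {
  validObject(geometry)
  c(row = geometry@fovMm[1] / geometry@matrixRows,
    col = geometry@fovMm[2] / geometry@matrixCols)
})

#' Voxel unit volume of a scan geometry
#'
#' Product of the two in-plane resolutions and the slice thickness; used to
#' convert flagged-voxel counts into lesion volumes. For the default
#' geometry (128 x 128 over 15 x 15 mm, 0.5 mm slices) it is
#' 0.006866... ~ 0.007 mm^3.
#'
#' @param geometry a [ScanGeometry-class].
#' @return voxel volume in mm^3.
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ScanGeometry", function(geometry) {
  res <- inplaneResolution(geometry)
  unname(res["row"] * res["col"] * geometry@sliceThicknessMm)
})

#' @name accessors
#' @title Accessors for radnec S4 objects
#' @description Slot accessors: `intensities()`, `geometry()`, `modality()`,
#'   `subjectId()` and `imagingWeek()` for [ImageVolume-class] (and, where
#'   meaningful, [LesionResult-class]); `totalDose()` for
#'   [FractionationScheme-class]; `lesionMask()` and `lesionVolume()` for
#'   [LesionResult-class]; `anovaTable()` and `pairwiseTable()` for
#'   [AnovaTukeyReport-class].
#' @param x,scheme the object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setMethod("intensities", "ImageVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("geometry", "ImageVolume", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("subjectId", "ImageVolume", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("imagingWeek", "ImageVolume", function(x) x@week)

#' @rdname accessors
#' @export
setMethod("totalDose", "FractionationScheme", function(scheme) scheme@n * scheme@d)

#' @rdname accessors
#' @export
setMethod("lesionMask", "LesionResult", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("lesionVolume", "LesionResult", function(x) x@volumeMm3)

#' @rdname accessors
#' @export
setMethod("modality", "LesionResult", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("subjectId", "LesionResult", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("imagingWeek", "LesionResult", function(x) x@week)

#' @rdname accessors
#' @export
setMethod("anovaTable", "AnovaTukeyReport", function(x) x@anova)

#' @rdname accessors
#' @export
setMethod("pairwiseTable", "AnovaTukeyReport", function(x) x@pairwise)

setMethod("show", "ScanGeometry", function(object) {
  res <- inplaneResolution(object)
  cat(sprintf(
    "ScanGeometry: %d x %d over %g x %g mm (%.4f x %.4f mm/px), %d slices x %g mm\n",
    object@matrixRows, object@matrixCols, object@fovMm[1], object@fovMm[2],
    res["row"], res["col"], object@nSlices, object@sliceThicknessMm))
  cat(sprintf("  voxel volume: %.6f mm^3\n", voxelVolume(object)))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ImageVolume '%s' (%s, week %g): %d x %d x %d (slice,row,col)\n",
              object@subjectId, object@modality, object@week, d[1], d[2], d[3]))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "FractionationScheme", function(object) {
  cat(sprintf("FractionationScheme '%s': %d x %g Gy (total %g Gy)\n",
              object@label, object@n, object@d, object@n * object@d))
})

setMethod("show", "DoseMetrics", function(object) {
  cat(sprintf("DoseMetrics for '%s' at alpha/beta = %g Gy: BED %.4g Gy, SFED %.4g Gy\n",
              object@scheme@label, object@alphaBeta, object@bed, object@sfed))
})

setMethod("show", "ReferenceStats", function(object) {
  cat(sprintf(
    "ReferenceStats (%s): mean %.4g, sd %.4g over %d voxels from %d subject(s)\n",
    object@modality, object@mean, object@sd, object@nVoxels,
    length(object@sourceSubjects)))
})

setMethod("show", "IntensityThresholds", function(object) {
  cat(sprintf("IntensityThresholds: [%.4g, %.4g] (k = %g)\n",
              object@lower, object@upper, object@k))
})

setMethod("show", "LesionResult", function(object) {
  cat(sprintf(
    "LesionResult '%s' (%s, week %g): %d hyper + %d hypo voxels = %.4g mm^3\n",
    object@subjectId, object@modality, object@week, object@nHyper,
    object@nHypo, object@volumeMm3))
})

setMethod("show", "AnovaTukeyReport", function(object) {
  cat("AnovaTukeyReport\n")
  cat("ANOVA:\n")
  print(object@anova, row.names = FALSE)
  cat(sprintf("Pairwise (Tukey-adjusted): %d comparisons\n",
              nrow(object@pairwise)))
  if (nzchar(object@note)) cat("Note: ", object@note, "\n", sep = "")
})
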