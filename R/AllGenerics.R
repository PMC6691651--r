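#' @rdname inplaneResolution
#' @export
setGeneric("inplaneResolution", function(geometry) standardGeneric("inplaneResolution"))

#' @rdname voxelVolume
#' @export
setGeneric("voxelVolume", function(geometry) standardGeneric("voxelVolume"))

#' @rdname bed
#' @export
setGeneric("bed", function(scheme, alphaBeta) standardGeneric("bed"))

#' @rdname doseMetrics
#' @export
setGeneric("doseMetrics", function(scheme, alphaBeta) standardGeneric("doseMetrics"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("imagingWeek", function(x) standardGeneric("imagingWeek"))

#' @rdname accessors
#' @export
setGeneric("totalDose", function(scheme) standardGeneric("totalDose"))

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))

#' @rdname accessors
#' @export
setGeneric("lesionVolume", function(x) standardGeneric("lesionVolume"))

#' @rdname accessors
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname accessors
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))
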