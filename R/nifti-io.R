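#' Read a 3-D MRI volume from a NIfTI-1 file
#'
#' Loads a `.nii`/`.nii.gz` file into an [ImageVolume-class]. The array is
#' interpreted in (slice, row, col) order: the first array dimension is the
#' slice stack and the NIfTI pixdim is `(sliceThickness, rowRes, colRes)` in
#' mm, matching what [writeVolume()] produces.
#'
#' @param path path to a NIfTI-1 file.
#' @param expectedGeometry optional [ScanGeometry-class]; if supplied the
#'   file header must match its dimensions exactly and its voxel spacings to
#'   within 1e-3 mm, otherwise an error reports expected vs found.
#' @param modality,subjectId,week metadata attached to the returned object.
#' @return an [ImageVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, expectedGeometry = NULL, modality = "T2",
                       subjectId = "unknown", week = 0) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), "-D in: ", path)
  pd <- RNifti::pixdim(img)
  geom <- ScanGeometry(matrixRows = d[2], matrixCols = d[3],
                       fovMm = c(d[2] * pd[2], d[3] * pd[3]),
                       nSlices = d[1], sliceThicknessMm = pd[1])
  if (!is.null(expectedGeometry)) {
    eg <- expectedGeometry
    expDim <- c(eg@nSlices, eg@matrixRows, eg@matrixCols)
    expPd <- c(eg@sliceThicknessMm, unname(inplaneResolution(eg)))
    if (!identical(as.integer(d), as.integer(expDim)) ||
        any(abs(pd[1:3] - expPd) > 1e-3)) {
      stop(sprintf(
        "geometry mismatch in %s: expected %s voxels at %s mm, found %s voxels at %s mm",
        path,
        paste(expDim, collapse = "x"),
        paste(signif(expPd, 6), collapse = "x"),
        paste(d, collapse = "x"),
        paste(signif(pd[1:3], 6), collapse = "x")))
    }
    geom <- expectedGeometry
  }
  arr <- array(as.numeric(img), dim = d)
  ImageVolume(arr, geom, modality = modality, subjectId = subjectId,
              week = week)
}

#' Write an [ImageVolume-class] to a NIfTI-1 file
#'
#' Intensities round-trip bit-exactly through [readVolume()]; voxel spacings
#' are stored in the header in mm.
#'
#' @param volume an [ImageVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  g <- volume@geometry
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- c(g@sliceThicknessMm, unname(inplaneResolution(g)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
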