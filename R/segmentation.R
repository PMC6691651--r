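# Threshold-based lesion segmentation: reference statistics from normal
# cohorts, +/- k SD cut-offs, brain masking, and voxel-count volumetry.

# --- low-level 3-D morphology / labelling helpers -------------------------

# shift a 3-D array by an integer offset, padding with `fill`
.shift3d <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.offsets27 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

.dilate3 <- function(mask) {
  out <- mask
  for (j in seq_len(nrow(.offsets27))) {
    o <- .offsets27[j, ]
    if (all(o == 0)) next
    out <- out | .shift3d(mask, o)
  }
  out
}

.erode3 <- function(mask) {
  out <- mask
  for (j in seq_len(nrow(.offsets27))) {
    o <- .offsets27[j, ]
    if (all(o == 0)) next
    out <- out & .shift3d(mask, o, fill = FALSE)
  }
  out
}

# morphological closing with a 3^3 structuring element
.close3 <- function(mask) .erode3(.dilate3(mask))

# connected-component labels of a 3-D logical mask (6- or 26-connectivity),
# via the voxel-adjacency graph
.labelComponents <- function(mask, connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  compact <- integer(prod(d))
  compact[idx] <- seq_along(idx)
  if (connectivity == 6L) {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- .offsets27[rowSums(abs(.offsets27)) > 0, , drop = FALSE]
    # half-space of offsets: each unordered neighbour pair appears once
    keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    offs <- g[keep, , drop = FALSE]
  }
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (j in seq_len(nrow(offs))) {
    o <- offs[j, ]
    nb <- co + matrix(o, nrow(co), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nbl <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- compact[nbl] > 0L
    edges[[j]] <- cbind(compact[idx][ok][hit], compact[nbl[hit]])
  }
  E <- do.call(rbind, edges)
  gr <- if (is.null(E) || nrow(E) == 0L) {
    igraph::make_empty_graph(n = length(idx), directed = FALSE)
  } else {
    igraph::make_graph(edges = as.vector(t(E)), n = length(idx),
                       directed = FALSE)
  }
  lab[idx] <- as.integer(igraph::components(gr)$membership)
  lab
}

# --- reference statistics and thresholds ----------------------------------

#' Pooled reference intensity statistics from a normal cohort
#'
#' Pools all brain-masked voxel intensities over the control volumes of one
#' modality and returns their mean and (n-1) standard deviation. These are
#' cohort statistics: voxels from all control subjects are pooled, not
#' averaged per subject.
#'
#' @param controlVolumes a list of [ImageVolume-class] objects (a single
#'   object is accepted) of lesion-free control subjects.
#' @param brainMasks a list of 3-D logical arrays, one per volume, each
#'   matching that volume's grid; a single array is recycled.
#' @param modality which modality to pool (`"T2"` or `"T1post"`); volumes of
#'   other modalities are ignored.
#' @return a [ReferenceStats-class].
#' @seealso [thresholds()], [segmentLesion()]
#' @export
computeReferenceStats <- function(controlVolumes, brainMasks, modality = "T2") {
  if (is(controlVolumes, "ImageVolume")) controlVolumes <- list(controlVolumes)
  if (is.array(brainMasks) && !is.list(brainMasks)) brainMasks <- list(brainMasks)
  if (length(brainMasks) == 1L && length(controlVolumes) > 1L)
    brainMasks <- rep(brainMasks, length(controlVolumes))
  if (length(controlVolumes) == 0L)
    stop("empty control cohort")
  if (length(brainMasks) != length(controlVolumes))
    stop("need one brain mask per control volume")
  sel <- vapply(controlVolumes, function(v) v@modality == modality, logical(1))
  if (!any(sel))
    stop("no control volumes of modality '", modality, "' in the cohort")
  vox <- unlist(lapply(which(sel), function(i) {
    v <- controlVolumes[[i]]
    m <- brainMasks[[i]]
    if (!identical(dim(m), dim(v@intensities)))
      stop("brain mask shape does not match volume for subject ", v@subjectId)
    if (!any(m)) stop("empty brain mask for subject ", v@subjectId)
    v@intensities[m]
  }))
  if (length(vox) < 2L) stop("need at least 2 pooled voxels")
  s <- stats::sd(vox)
  if (!is.finite(s) || s <= 0)
    stop("degenerate reference: pooled intensity standard deviation is zero")
  new("ReferenceStats", modality = modality, mean = mean(vox), sd = s,
      nVoxels = length(vox),
      sourceSubjects = unique(vapply(controlVolumes[sel],
                                     function(v) v@subjectId, character(1))))
}

#' Intensity thresholds at mean +/- k SD
#'
#' Both cut-offs sit `k` standard deviations from the normal-cohort mean;
#' voxels above the upper cut-off are hyperintense, below the lower cut-off
#' hypointense. The default `k = 2` flags ~4.55% of purely normal Gaussian
#' voxels (the two 2-SD tails).
#'
#' @param stats a [ReferenceStats-class].
#' @param k positive SD multiplier (default 2).
#' @return an [IntensityThresholds-class].
#' @export
thresholds <- function(stats, k = 2) {
  stopifnot(is(stats, "ReferenceStats"))
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a strictly positive scalar")
  new("IntensityThresholds", lower = stats@mean - k * stats@sd,
      upper = stats@mean + k * stats@sd, k = as.numeric(k))
}

# --- brain masking --------------------------------------------------------

#' Brain mask for a volume
#'
#' Either returns a user-supplied mask verbatim (`method = "provided"`), or
#' derives one automatically: global Otsu threshold on the intensity
#' histogram, largest 6-connected foreground component, then morphological
#' closing with a 3^3 structuring element. The automatic method is
#' deterministic for a fixed volume.
#'
#' @param volume an [ImageVolume-class].
#' @param method `"auto"` or `"provided"`.
#' @param mask for `method = "provided"`, a 3-D logical array matching the
#'   volume grid.
#' @return a 3-D logical array.
#' @export
brainMask <- function(volume, method = c("auto", "provided"), mask = NULL) {
  stopifnot(is(volume, "ImageVolume"))
  method <- match.arg(method)
  if (method == "provided") {
    if (is.null(mask)) stop("method = 'provided' requires a mask")
    if (!identical(dim(mask), dim(volume@intensities)))
      stop("provided mask shape does not match the volume")
    mask <- mask != 0
    if (!any(mask)) stop("no brain found: provided mask is empty")
    return(mask)
  }
  v <- volume@intensities
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("no brain found: volume has constant intensity")
  x01 <- (v - rng[1]) / (rng[2] - rng[1])
  # one global Otsu cut on the flattened voxel histogram
  th <- EBImage::otsu(matrix(as.vector(x01), ncol = 1L))
  fg <- array(x01 > th, dim = dim(v))
  if (!any(fg)) stop("no brain found: Otsu foreground is empty")
  lab <- .labelComponents(fg, connectivity = 6L)
  sizes <- tabulate(lab[lab > 0L])
  out <- .close3(lab == which.max(sizes))
  if (!any(out)) stop("no brain found: mask empty after morphology")
  out
}

# --- segmentation and volumetry -------------------------------------------

#' Threshold-based lesion segmentation of one volume
#'
#' Flags brain-masked voxels whose intensity falls outside the
#' `[lower, upper]` reference band: above `upper` as hyperintense, below
#' `lower` as hypointense. Lesion is the union of both, and lesion volume is
#' the flagged voxel count times the voxel unit volume of the scan geometry.
#' T1 and T2 volumes are segmented independently with their own reference
#' statistics; no cross-modality fusion is performed.
#'
#' @param volume an [ImageVolume-class].
#' @param mask 3-D logical brain mask matching the volume grid.
#' @param thr an [IntensityThresholds-class].
#' @param minClusterVoxels drop flagged 26-connected clusters smaller than
#'   this many voxels (default 0: keep everything).
#' @return a [LesionResult-class].
#' @export
segmentLesion <- function(volume, mask, thr, minClusterVoxels = 0L) {
  stopifnot(is(volume, "ImageVolume"), is(thr, "IntensityThresholds"))
  v <- volume@intensities
  if (!identical(dim(mask), dim(v)))
    stop("brain mask shape does not match the volume")
  mask <- mask != 0
  hyper <- mask & (v > thr@upper)
  hypo <- mask & (v < thr@lower)
  flagged <- hyper | hypo
  if (minClusterVoxels > 0L && any(flagged)) {
    lab <- .labelComponents(flagged, connectivity = 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- array(lab > 0L & sizes[pmax(lab, 1L)] >= minClusterVoxels,
                  dim = dim(lab))
    hyper <- hyper & keep
    hypo <- hypo & keep
    flagged <- flagged & keep
  }
  vv <- voxelVolume(volume@geometry)
  nHyper <- sum(hyper)
  nHypo <- sum(hypo)
  new("LesionResult", mask = flagged, nHyper = as.integer(nHyper),
      nHypo = as.integer(nHypo), volumeMm3 = (nHyper + nHypo) * vv,
      voxelVolumeMm3 = vv, thresholds = thr, modality = volume@modality,
      subjectId = volume@subjectId, week = volume@week)
}

#' Batch volumetry over a cohort manifest
#'
#' Runs [segmentLesion()] for every non-control manifest row and returns one
#' measurement record per (subject, week, modality). Thresholds are derived
#' per modality from the supplied reference statistics, and the cut-offs
#' used are recorded in each output row. Rows whose volume file cannot be
#' read are skipped with a warning; the number of failures is attached as
#' `attr(result, "nFailed")`.
#'
#' @param manifest a data.frame (or path to a CSV) with columns
#'   `subject_id`, `scheme_label`, `week`, `modality`, `path`, and optional
#'   `is_control` (control rows are skipped) and `mask_path` (per-volume
#'   brain mask NIfTI; otherwise the automatic mask is used).
#' @param referenceStats a [ReferenceStats-class] or a list of them; a
#'   matching modality must be available for every measured row.
#' @param k SD multiplier passed to [thresholds()].
#' @param minClusterVoxels passed to [segmentLesion()].
#' @param expectedGeometry optional [ScanGeometry-class] enforced on every
#'   file read.
#' @param verbose log the per-modality cut-offs with `message()`.
#' @return a data.frame with columns `subject_id`, `scheme_label`, `week`,
#'   `modality`, `n_hyper`, `n_hypo`, `volume_mm3`, `thr_lower`, `thr_upper`.
#' @export
volumetryBatch <- function(manifest, referenceStats, k = 2,
                           minClusterVoxels = 0L, expectedGeometry = NULL,
                           verbose = FALSE) {
  if (is.character(manifest)) manifest <- readCohortCsv(manifest)
  need <- c("subject_id", "scheme_label", "week", "modality", "path")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  if (is(referenceStats, "ReferenceStats"))
    referenceStats <- list(referenceStats)
  statMods <- vapply(referenceStats, function(s) s@modality, character(1))
  thrByMod <- lapply(referenceStats, thresholds, k = k)
  names(thrByMod) <- statMods
  if (verbose) for (m in statMods)
    message(sprintf("modality %s: thresholds [%.6g, %.6g] (k = %g)",
                    m, thrByMod[[m]]@lower, thrByMod[[m]]@upper, k))
  rows <- manifest
  if ("is_control" %in% names(rows)) rows <- rows[!(rows$is_control %in% 1), ]
  out <- vector("list", nrow(rows))
  nFailed <- 0L
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    rec <- tryCatch({
      if (!(r$modality %in% statMods))
        stop("no reference statistics for modality '", r$modality, "'")
      vol <- readVolume(r$path, expectedGeometry = expectedGeometry,
                        modality = r$modality, subjectId = r$subject_id,
                        week = r$week)
      bm <- if ("mask_path" %in% names(r) && !is.na(r$mask_path) &&
                nzchar(r$mask_path)) {
        brainMask(vol, "provided",
                  mask = array(as.numeric(RNifti::readNifti(r$mask_path)) != 0,
                               dim = dim(vol@intensities)))
      } else {
        brainMask(vol, "auto")
      }
      thr <- thrByMod[[r$modality]]
      les <- segmentLesion(vol, bm, thr, minClusterVoxels = minClusterVoxels)
      data.frame(subject_id = r$subject_id, scheme_label = r$scheme_label,
                 week = r$week, modality = r$modality,
                 n_hyper = les@nHyper, n_hypo = les@nHypo,
                 volume_mm3 = les@volumeMm3, thr_lower = thr@lower,
                 thr_upper = thr@upper, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("skipping %s week %s (%s): %s", r$subject_id, r$week,
                      r$modality, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(rec)) nFailed <- nFailed + 1L else out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(subject_id = character(), scheme_label = character(),
                      week = numeric(), modality = character(),
                      n_hyper = integer(), n_hypo = integer(),
                      volume_mm3 = numeric(), thr_lower = numeric(),
                      thr_upper = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (nrow(rows) == 0L) warning("manifest has no measurement rows")
  attr(res, "nFailed") <- nFailed
  res
}
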