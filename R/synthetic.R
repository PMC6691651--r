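# Seeded synthetic phantoms and longitudinal cohorts with known ground
# truth. Phantoms emulate the statistical structure the threshold
# segmentation assumes: an ellipsoidal "brain" of i.i.d. Gaussian voxels on
# a dark background, with optional contiguous lesions offset from the brain
# mean by a stated number of SDs.

.ellipsoidMaskVox <- function(dims, center, semiAxes) {
  sl <- slice.index(array(0L, dims), 1L)
  ro <- slice.index(array(0L, dims), 2L)
  co <- slice.index(array(0L, dims), 3L)
  ((sl - center[1]) / semiAxes[1])^2 + ((ro - center[2]) / semiAxes[2])^2 +
    ((co - center[3]) / semiAxes[3])^2 <= 1
}

# rasterise a lesion of a target volume (mm^3) into voxel space
.lesionMaskFor <- function(geometry, center, shape, targetVolumeMm3) {
  res <- c(geometry@sliceThicknessMm, unname(inplaneResolution(geometry)))
  dims <- c(geometry@nSlices, geometry@matrixRows, geometry@matrixCols)
  if (shape == "ellipsoid") {
    r <- (3 * targetVolumeMm3 / (4 * pi))^(1 / 3)
    .ellipsoidMaskVox(dims, center, pmax(r / res, 1e-9))
  } else if (shape == "block") {
    half <- (targetVolumeMm3^(1 / 3) / 2) / res
    sl <- slice.index(array(0L, dims), 1L)
    ro <- slice.index(array(0L, dims), 2L)
    co <- slice.index(array(0L, dims), 3L)
    abs(sl - center[1]) <= half[1] & abs(ro - center[2]) <= half[2] &
      abs(co - center[3]) <= half[3]
  } else stop("unknown lesion shape: ", shape)
}

#' Specify a synthetic phantom volume
#'
#' A phantom is an ellipsoidal brain of i.i.d. `Normal(brainMean, brainSd)`
#' voxels on a constant background, optionally containing one contiguous
#' lesion whose intensities are offset from the brain mean by
#' `offsetSd * brainSd` (positive = hyperintense, negative = hypointense).
#' The lesion is rasterised to approximate `targetVolumeMm3`; the realised
#' voxel count is reported by [generatePhantom()].
#'
#' @param geometry a [ScanGeometry-class] (default: the 21 x 128 x 128,
#'   15 mm FOV, 0.5 mm protocol).
#' @param brainCenter,brainSemiAxes ellipsoid centre and semi-axes in voxel
#'   units (slice, row, col); defaults place a ~415 mm^3 brain centrally.
#' @param backgroundLevel constant background intensity.
#' @param brainMean,brainSd brain voxel intensity distribution; `brainSd`
#'   may be 0 for noise-free phantoms.
#' @param lesion `NULL` for a lesion-free phantom, or a list with elements
#'   `center` (voxel coords; default in one hemisphere), `shape`
#'   (`"ellipsoid"` or `"block"`), `targetVolumeMm3` and `offsetSd`.
#' @param modality,subjectId,week metadata for the generated
#'   [ImageVolume-class].
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return a `PhantomSpec` (validated list).
#' @seealso [generatePhantom()]
#' @export
phantomSpec <- function(geometry = ScanGeometry(), brainCenter = NULL,
                        brainSemiAxes = NULL, backgroundLevel = 0,
                        brainMean = 500, brainSd = 25, lesion = NULL,
                        modality = "T2", subjectId = "phantom", week = 0,
                        seed = 1L) {
  validObject(geometry)
  dims <- c(geometry@nSlices, geometry@matrixRows, geometry@matrixCols)
  if (is.null(brainCenter)) brainCenter <- (dims + 1) / 2
  if (is.null(brainSemiAxes))
    brainSemiAxes <- pmax(1, c(0.85 * dims[1] / 2, 0.63 * dims[2] / 2,
                               0.63 * dims[3] / 2))
  if (!is.finite(brainSd) || brainSd < 0) stop("brainSd must be >= 0")
  if (!is.null(lesion)) {
    if (is.null(lesion$center))
      lesion$center <- brainCenter + c(0, 0, brainSemiAxes[3] / 4)
    if (is.null(lesion$shape)) lesion$shape <- "ellipsoid"
    if (is.null(lesion$targetVolumeMm3) || lesion$targetVolumeMm3 <= 0)
      stop("lesion needs a positive targetVolumeMm3")
    if (is.null(lesion$offsetSd) || !is.finite(lesion$offsetSd) ||
        lesion$offsetSd == 0)
      stop("lesion needs a non-zero offsetSd")
  }
  structure(list(geometry = geometry, brainCenter = brainCenter,
                 brainSemiAxes = brainSemiAxes,
                 backgroundLevel = backgroundLevel, brainMean = brainMean,
                 brainSd = brainSd, lesion = lesion, modality = modality,
                 subjectId = subjectId, week = week,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a phantom volume with ground-truth masks
#'
#' Deterministic for a fixed spec (including its seed): the same spec yields
#' bit-identical volumes.
#'
#' @param spec a [phantomSpec()].
#' @return a list with elements `volume` ([ImageVolume-class]), `brainMask`
#'   and `lesionMask` (3-D logical arrays), and `lesionVoxels` (the realised
#'   lesion voxel count).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  g <- spec$geometry
  dims <- c(g@nSlices, g@matrixRows, g@matrixCols)
  set.seed(spec$seed)
  brain <- .ellipsoidMaskVox(dims, spec$brainCenter, spec$brainSemiAxes)
  if (!any(brain)) stop("brain ellipsoid contains no voxels")
  v <- array(spec$backgroundLevel, dims)
  v[brain] <- stats::rnorm(sum(brain), spec$brainMean, spec$brainSd)
  lesionMask <- array(FALSE, dims)
  if (!is.null(spec$lesion)) {
    lesionMask <- .lesionMaskFor(g, spec$lesion$center, spec$lesion$shape,
                                 spec$lesion$targetVolumeMm3)
    if (any(lesionMask & !brain))
      stop("lesion extends outside the brain ellipsoid")
    v[lesionMask] <- v[lesionMask] + spec$lesion$offsetSd * spec$brainSd
  }
  list(volume = ImageVolume(v, g, modality = spec$modality,
                            subjectId = spec$subjectId, week = spec$week),
       brainMask = brain, lesionMask = lesionMask,
       lesionVoxels = sum(lesionMask))
}

#' Saturating lesion growth model
#'
#' Expected lesion volume is zero before onset and follows
#' `plateau * (1 - exp(-rate * (t - onset)))` thereafter: non-decreasing and
#' approaching the plateau. Observations after an arm's censor week are
#' missing (`NA`), emulating early sacrifice of that arm.
#'
#' @param plateauMm3 asymptotic lesion volume (mm^3).
#' @param ratePerWeek exponential approach rate (1/week).
#' @param onsetWeek week at which the lesion first appears (default 3).
#' @param censorWeek optional; weeks strictly after this are censored.
#' @return a `GrowthModelParams` (validated list).
#' @export
growthModelParams <- function(plateauMm3, ratePerWeek = 1, onsetWeek = 3,
                              censorWeek = NULL) {
  if (!is.finite(plateauMm3) || plateauMm3 <= 0) stop("plateauMm3 must be > 0")
  if (!is.finite(ratePerWeek) || ratePerWeek <= 0) stop("ratePerWeek must be > 0")
  if (!is.finite(onsetWeek) || onsetWeek < 0) stop("onsetWeek must be >= 0")
  structure(list(plateauMm3 = plateauMm3, ratePerWeek = ratePerWeek,
                 onsetWeek = onsetWeek, censorWeek = censorWeek),
            class = "GrowthModelParams")
}

#' Expected lesion volume under the growth model
#'
#' @param params a [growthModelParams()].
#' @param week non-negative week(s) post-irradiation; vectorised.
#' @return expected volume in mm^3; `NA` for censored weeks.
#' @examples
#' p <- growthModelParams(plateauMm3 = 10, ratePerWeek = 1, onsetWeek = 3)
#' growthCurve(p, 4)  # 10 * (1 - exp(-1)) ~ 6.321
#' @export
growthCurve <- function(params, week) {
  stopifnot(inherits(params, "GrowthModelParams"))
  if (any(!is.finite(week)) || any(week < 0))
    stop("week must be non-negative")
  out <- ifelse(week < params$onsetWeek, 0,
                params$plateauMm3 *
                  (1 - exp(-params$ratePerWeek * (week - params$onsetWeek))))
  if (!is.null(params$censorWeek)) out[week > params$censorWeek] <- NA_real_
  out
}

#' One arm of a cohort design
#'
#' @param schemeLabel label such as `"5x20"` or `"1x90"`.
#' @param nSubjects number of animals in the arm (>= 1).
#' @param growth a [growthModelParams()] describing the arm's expected
#'   lesion trajectory.
#' @return an `ArmSpec` list.
#' @export
armSpec <- function(schemeLabel, nSubjects, growth) {
  stopifnot(inherits(growth, "GrowthModelParams"), nSubjects >= 1)
  structure(list(schemeLabel = schemeLabel,
                 nSubjects = as.integer(nSubjects), growth = growth),
            class = "ArmSpec")
}

#' Longitudinal cohort design
#'
#' Defines the arms, imaging schedule, modalities, intensity model and noise
#' structure of a synthetic cohort. Subject-level heterogeneity is a
#' lognormal frailty multiplying each subject's growth curve; measurement
#' noise is additive Gaussian on the target lesion volume (truncated at 0).
#'
#' @param arms list of [armSpec()] objects.
#' @param weeks imaging timepoints (ascending).
#' @param modalities subset of `c("T2", "T1post")`.
#' @param noiseSdMm3 SD of additive volume noise (mm^3).
#' @param frailtySdLog SD of the log-normal subject frailty.
#' @param nControls lesion-free control subjects (imaged once, week 0).
#' @param geometry a [ScanGeometry-class] for all phantoms.
#' @param intensity per-modality intensity model: named list of
#'   `list(mean, sd, offsetSd)`.
#' @param seed integer seed; cohort generation is a pure function of
#'   (design, seed).
#' @return a `CohortDesign` list.
#' @seealso [generateCohort()], [defaultCohortDesign()]
#' @export
cohortDesign <- function(arms, weeks = c(1, 2, 3, 4, 6),
                         modalities = c("T2", "T1post"), noiseSdMm3 = 0.5,
                         frailtySdLog = 0.2, nControls = 4L,
                         geometry = ScanGeometry(),
                         intensity = list(
                           T2 = list(mean = 500, sd = 25, offsetSd = 5),
                           T1post = list(mean = 400, sd = 20, offsetSd = 5)),
                         seed = 1L) {
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, logical(1), "ArmSpec")))
  if (is.unsorted(weeks, strictly = TRUE)) stop("weeks must be sorted ascending")
  if (!all(modalities %in% .MODALITIES))
    stop("modalities must be a subset of: ", paste(.MODALITIES, collapse = ", "))
  if (!all(modalities %in% names(intensity)))
    stop("intensity model missing for some modalities")
  structure(list(arms = arms, weeks = weeks, modalities = modalities,
                 noiseSdMm3 = noiseSdMm3, frailtySdLog = frailtySdLog,
                 nControls = as.integer(nControls), geometry = geometry,
                 intensity = intensity, seed = as.integer(seed)),
            class = "CohortDesign")
}

#' Default cohort design mirroring the reference study structure
#'
#' Four fractionated arms (5x20, 10x10, 5x18, 10x9 Gy) plus single-fraction
#' 80, 90 and 100 Gy comparison arms; lesion onset at week 3 (week 2 for the
#' 100 Gy arm, which is censored after week 2, emulating early sacrifice);
#' imaging at weeks 1--6. Plateau volumes order the arms by total dose. The
#' quantitative plateaus are illustrative defaults, not reproductions of any
#' measured volumes.
#'
#' @param nPerArm subjects per arm (the censored 100 Gy arm gets
#'   `max(2, nPerArm %/% 2)`).
#' @param geometry passed to [cohortDesign()].
#' @param seed passed to [cohortDesign()].
#' @return a `CohortDesign`.
#' @export
defaultCohortDesign <- function(nPerArm = 6L, geometry = ScanGeometry(),
                                seed = 1L) {
  arms <- list(
    armSpec("5x20", nPerArm, growthModelParams(12, 1.0, 3)),
    armSpec("10x10", nPerArm, growthModelParams(10, 1.0, 3)),
    armSpec("5x18", nPerArm, growthModelParams(8, 0.9, 3)),
    armSpec("10x9", nPerArm, growthModelParams(7, 0.9, 3)),
    armSpec("1x80", nPerArm, growthModelParams(8, 0.9, 3)),
    armSpec("1x90", nPerArm, growthModelParams(12, 1.0, 3)),
    armSpec("1x100", max(2L, nPerArm %/% 2L),
            growthModelParams(15, 1.2, 2, censorWeek = 2)))
  cohortDesign(arms, geometry = geometry, seed = seed)
}

# ordinal histology grade (0-3) from a subject's asymptotic lesion volume
.histologyGrade <- function(finalVolumeMm3) {
  as.integer(cut(finalVolumeMm3, breaks = c(-Inf, 2, 6, 12, Inf))) - 1L
}

#' Generate a synthetic longitudinal cohort on disk
#'
#' Writes one NIfTI phantom per (subject, week, modality) plus lesion-free
#' control phantoms, together with `manifest.csv` (directly consumable by
#' [volumetryBatch()]), `truth.csv` (the generated ground truth, including
#' realised lesion voxel counts) and `histology.csv` (ordinal 0--3 grades
#' derived from each subject's asymptotic lesion volume). Arms with a
#' censor week emit no records after it. The whole cohort is a pure
#' function of (design, seed).
#'
#' @param design a [cohortDesign()].
#' @param outDir output directory (created if needed).
#' @param seed overrides `design$seed` if given.
#' @return a list with `manifest`, `truth` and `histology` data.frames and
#'   `dir`, the output directory. The CSVs are also written under `outDir`.
#' @export
generateCohort <- function(design, outDir, seed = design$seed) {
  stopifnot(inherits(design, "CohortDesign"))
  volDir <- file.path(outDir, "volumes")
  dir.create(volDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(volDir)) stop("cannot create output directory: ", volDir)
  g <- design$geometry
  vv <- voxelVolume(g)

  # fixed-order schedule of all phantoms
  subj <- do.call(rbind, lapply(design$arms, function(a) {
    data.frame(subject_id = sprintf("%s_s%02d", a$schemeLabel,
                                    seq_len(a$nSubjects)),
               scheme_label = a$schemeLabel, arm = a$schemeLabel,
               stringsAsFactors = FALSE)
  }))
  growthByArm <- stats::setNames(lapply(design$arms, `[[`, "growth"),
                                 vapply(design$arms, `[[`, character(1),
                                        "schemeLabel"))
  sched <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    gp <- growthByArm[[subj$arm[i]]]
    wk <- design$weeks
    if (!is.null(gp$censorWeek)) wk <- wk[wk <= gp$censorWeek]
    if (!length(wk)) return(NULL)
    expand.grid(subject_id = subj$subject_id[i], week = wk,
                modality = design$modalities, stringsAsFactors = FALSE)
  }))
  sched <- merge(sched, subj[c("subject_id", "scheme_label")],
                 by = "subject_id", sort = FALSE)
  sched <- sched[order(sched$subject_id, sched$week, sched$modality), ]

  # all randomness drawn here, in one fixed order, from one seed
  set.seed(as.integer(seed))
  frailty <- stats::setNames(
    stats::rlnorm(nrow(subj), 0, design$frailtySdLog), subj$subject_id)
  noise <- stats::rnorm(nrow(sched), 0, design$noiseSdMm3)
  nControlScans <- design$nControls * length(design$modalities)
  phantomSeeds <- sample.int(.Machine$integer.max - 1L,
                             nrow(sched) + nControlScans)

  expected <- vapply(seq_len(nrow(sched)), function(i) {
    growthCurve(growthByArm[[sched$scheme_label[i]]], sched$week[i])
  }, numeric(1))
  target <- pmax(0, expected * frailty[sched$subject_id] + noise)
  target[expected == 0] <- 0  # no lesion before onset

  manifest <- truth <- vector("list", nrow(sched) + nControlScans)
  for (i in seq_len(nrow(sched))) {
    r <- sched[i, ]
    im <- design$intensity[[r$modality]]
    lesion <- if (target[i] >= vv)
      list(targetVolumeMm3 = target[i], offsetSd = im$offsetSd) else NULL
    spec <- phantomSpec(geometry = g, brainMean = im$mean, brainSd = im$sd,
                        lesion = lesion, modality = r$modality,
                        subjectId = r$subject_id, week = r$week,
                        seed = phantomSeeds[i])
    ph <- generatePhantom(spec)
    path <- file.path(volDir, sprintf("%s_w%g_%s.nii.gz", r$subject_id,
                                      r$week, r$modality))
    writeVolume(ph$volume, path)
    manifest[[i]] <- data.frame(
      subject_id = r$subject_id, scheme_label = r$scheme_label,
      week = r$week, modality = r$modality, path = path, is_control = 0L,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      subject_id = r$subject_id, scheme_label = r$scheme_label,
      week = r$week, modality = r$modality, true_target_mm3 = target[i],
      true_voxels = ph$lesionVoxels,
      true_volume_mm3 = ph$lesionVoxels * vv, stringsAsFactors = FALSE)
  }
  k <- nrow(sched)
  ctrl <- expand.grid(idx = seq_len(design$nControls),
                      modality = design$modalities, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(ctrl))) {
    im <- design$intensity[[ctrl$modality[j]]]
    sid <- sprintf("control_s%02d", ctrl$idx[j])
    spec <- phantomSpec(geometry = g, brainMean = im$mean, brainSd = im$sd,
                        lesion = NULL, modality = ctrl$modality[j],
                        subjectId = sid, week = 0,
                        seed = phantomSeeds[k + j])
    ph <- generatePhantom(spec)
    path <- file.path(volDir, sprintf("%s_w0_%s.nii.gz", sid, ctrl$modality[j]))
    writeVolume(ph$volume, path)
    manifest[[k + j]] <- data.frame(
      subject_id = sid, scheme_label = "control", week = 0,
      modality = ctrl$modality[j], path = path, is_control = 1L,
      stringsAsFactors = FALSE)
    truth[[k + j]] <- data.frame(
      subject_id = sid, scheme_label = "control", week = 0,
      modality = ctrl$modality[j], true_target_mm3 = 0, true_voxels = 0L,
      true_volume_mm3 = 0, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  histology <- data.frame(
    subject_id = subj$subject_id, scheme_label = subj$scheme_label,
    grade = .histologyGrade(
      vapply(subj$subject_id, function(s)
        growthByArm[[subj$arm[subj$subject_id == s]]]$plateauMm3, numeric(1)) *
        frailty[subj$subject_id]),
    stringsAsFactors = FALSE)
  rownames(manifest) <- rownames(truth) <- rownames(histology) <- NULL
  .writeCsv(manifest, file.path(outDir, "manifest.csv"))
  .writeCsv(truth, file.path(outDir, "truth.csv"))
  .writeCsv(histology, file.path(outDir, "histology.csv"))
  list(manifest = manifest, truth = truth, histology = histology,
       dir = outDir)
}
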