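# Synthetic phantom and cohort generator: determinism, ground truth,
# growth model, censoring

test_that("phantom generation is a pure function of its spec", {
  sp <- phantomSpec(geometry = smallGeometry(), seed = 77,
                    lesion = list(targetVolumeMm3 = 1, offsetSd = 5))
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(intensities(a$volume), intensities(b$volume))
  expect_identical(a$lesionMask, b$lesionMask)
  # a different seed changes the noise realisation
  c <- generatePhantom(phantomSpec(geometry = smallGeometry(), seed = 78,
                                   lesion = list(targetVolumeMm3 = 1,
                                                 offsetSd = 5)))
  expect_false(identical(intensities(a$volume), intensities(c$volume)))
})

test_that("phantom structure matches its spec", {
  sp <- phantomSpec(geometry = smallGeometry(), seed = 3, backgroundLevel = 7)
  ph <- generatePhantom(sp)
  v <- intensities(ph$volume)
  expect_true(all(v[!ph$brainMask] == 7))
  expect_equal(mean(v[ph$brainMask]), 500, tolerance = 1)
  expect_equal(sum(ph$lesionMask), 0)
  expect_equal(ph$lesionVoxels, sum(ph$lesionMask))
})

test_that("realised lesion voxel count stays within one boundary shell of target", {
  g <- ScanGeometry()
  vv <- voxelVolume(g)
  for (target in c(0.5, 2, 5, 12, 20)) {
    ph <- generatePhantom(phantomSpec(
      geometry = g, seed = 400 + round(target * 10),
      lesion = list(targetVolumeMm3 = target, offsetSd = 5)))
    shellMm3 <- outerShellVoxels(ph$lesionMask) * vv
    expect_lt(abs(ph$lesionVoxels * vv - target), shellMm3)
    expect_equal(ph$lesionVoxels, sum(ph$lesionMask))
  }
})

test_that("a lesion that does not fit inside the brain is rejected", {
  g <- smallGeometry()
  expect_error(generatePhantom(phantomSpec(
    geometry = g, seed = 1,
    lesion = list(targetVolumeMm3 = 25, offsetSd = 5))),
    "outside the brain")
  expect_error(phantomSpec(lesion = list(targetVolumeMm3 = -1, offsetSd = 5)),
               "positive targetVolumeMm3")
  expect_error(phantomSpec(lesion = list(targetVolumeMm3 = 1, offsetSd = 0)),
               "non-zero offsetSd")
})

test_that("noise-free lesions are recovered exactly by segmentation", {
  g <- smallGeometry()
  ph <- generatePhantom(phantomSpec(
    geometry = g, seed = 55, brainSd = 0,
    lesion = list(targetVolumeMm3 = 2, offsetSd = 1)))
  v <- intensities(ph$volume)
  v[ph$lesionMask] <- 500 + 125  # fixed absolute offset, zero background noise
  vol <- ImageVolume(v, g)
  res <- segmentLesion(vol, ph$brainMask, fixedThresholds(500, 25))
  expect_equal(res@nHyper + res@nHypo, sum(ph$lesionMask))
  expect_identical(res@mask, ph$lesionMask)
})

test_that("the growth model has onset, saturation and censoring", {
  p <- growthModelParams(plateauMm3 = 10, ratePerWeek = 1, onsetWeek = 3)
  expect_equal(growthCurve(p, c(0, 1, 2.9)), c(0, 0, 0))
  expect_equal(growthCurve(p, 4), 10 * (1 - exp(-1)))
  expect_equal(growthCurve(p, 4), 6.321, tolerance = 1e-3)
  expect_equal(growthCurve(p, 1e3), 10)
  wk <- seq(0, 12, by = 0.25)
  expect_true(all(diff(growthCurve(p, wk)) >= 0))
  pc <- growthModelParams(10, 1.2, 2, censorWeek = 2)
  expect_true(is.na(growthCurve(pc, 3)))
  expect_false(is.na(growthCurve(pc, 2)))
  expect_error(growthCurve(p, -1), "non-negative")
  expect_error(growthModelParams(-5), "plateauMm3")
})

smallDesign <- function(seed = 1L) {
  cohortDesign(
    arms = list(
      armSpec("5x20", 3, growthModelParams(4, 1, 3)),
      armSpec("10x9", 3, growthModelParams(2, 1, 3)),
      armSpec("1x100", 2, growthModelParams(8, 1.2, 2, censorWeek = 2))),
    weeks = c(2, 4, 6), modalities = "T2", noiseSdMm3 = 0.2,
    nControls = 2L, geometry = smallGeometry(), seed = seed)
}

test_that("cohort generation is deterministic and bookkeeps ground truth", {
  d1 <- tempfile("coh1"); d2 <- tempfile("coh2")
  c1 <- generateCohort(smallDesign(), d1)
  c2 <- generateCohort(smallDesign(), d2)
  expect_identical(c1$truth$true_voxels, c2$truth$true_voxels)
  expect_identical(c1$manifest[setdiff(names(c1$manifest), "path")],
                   c2$manifest[setdiff(names(c2$manifest), "path")])
  # identical volume bytes under the same seed
  expect_identical(unname(tools::md5sum(c1$manifest$path[1])),
                   unname(tools::md5sum(c2$manifest$path[1])))
  # censored arm emits nothing after its censor week
  cens <- c1$manifest[c1$manifest$scheme_label == "1x100", ]
  expect_true(all(cens$week <= 2))
  expect_gt(nrow(cens), 0)
  # controls are flagged and lesion-free in the truth table
  ctrl <- c1$truth[c1$truth$scheme_label == "control", ]
  expect_equal(nrow(ctrl), 2L)
  expect_true(all(ctrl$true_voxels == 0))
  # truth voxel counts convert exactly to volumes
  vv <- voxelVolume(smallGeometry())
  expect_equal(c1$truth$true_volume_mm3, c1$truth$true_voxels * vv)
  # histology grades on the 0-3 ordinal scale for every non-control subject
  expect_equal(nrow(c1$histology), 8L)
  expect_true(all(c1$histology$grade %in% 0:3))
  # CSVs round-trip
  m <- readCohortCsv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(m), nrow(c1$manifest))
})

test_that("generated lesions are recoverable end-to-end by the segmenter", {
  dir <- tempfile("rec")
  co <- generateCohort(smallDesign(seed = 9), dir)
  ctrlRows <- co$manifest[co$manifest$is_control == 1L, ]
  vols <- lapply(ctrlRows$path, readVolume)
  masks <- lapply(vols, brainMask)
  stats <- computeReferenceStats(vols, masks)
  out <- volumetryBatch(co$manifest, stats, minClusterVoxels = 27L)
  merged <- merge(out, co$truth,
                  by = c("subject_id", "scheme_label", "week", "modality"))
  expect_equal(nrow(merged), nrow(out))
  grown <- merged[merged$true_voxels > 200, ]
  expect_gt(nrow(grown), 0)
  # recovered within 35% of truth for well-developed lesions
  relErr <- abs(grown$volume_mm3 - grown$true_volume_mm3) /
    grown$true_volume_mm3
  expect_lt(stats::median(relErr), 0.35)
})
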