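# Reference statistics, thresholds, brain masking, lesion volumetry

test_that("reference statistics pool brain voxels across controls", {
  g <- ScanGeometry(8, 8, c(8, 8), 4, 1)
  mk <- function(fill, tweak = NULL) {
    a <- array(fill, c(4, 8, 8))
    if (!is.null(tweak)) a[tweak] <- a[tweak] + 4
    a
  }
  mask <- array(TRUE, c(4, 8, 8))
  v1 <- ImageVolume(mk(100), g, subjectId = "a")
  v2 <- ImageVolume(mk(100, tweak = 17), g, subjectId = "b")
  s <- computeReferenceStats(list(v1, v2), list(mask, mask))
  n <- 2 * 4 * 8 * 8
  expect_equal(s@mean, (100 * n + 4) / n)
  # direct (n-1) SD of the pooled voxels
  expect_equal(s@sd, sd(c(rep(100, n - 1), 104)))
  expect_gt(s@sd, 0)
  expect_equal(s@nVoxels, as.integer(n))
  expect_setequal(s@sourceSubjects, c("a", "b"))
})

test_that("a constant-intensity control cohort is rejected as degenerate", {
  g <- ScanGeometry(8, 8, c(8, 8), 4, 1)
  v <- ImageVolume(array(100, c(4, 8, 8)), g)
  expect_error(computeReferenceStats(v, array(TRUE, c(4, 8, 8))),
               "degenerate reference")
  expect_error(computeReferenceStats(list(), list()), "empty control cohort")
  expect_error(computeReferenceStats(v, array(TRUE, c(4, 8, 8)),
                                     modality = "T1post"),
               "no control volumes of modality")
})

test_that("pooled statistics converge to the generating parameters", {
  # two phantoms give > 1e5 pooled brain voxels ~ Normal(500, 25)
  phs <- lapply(c(21, 22), function(s) generatePhantom(phantomSpec(seed = s)))
  s <- computeReferenceStats(lapply(phs, `[[`, "volume"),
                             lapply(phs, `[[`, "brainMask"))
  expect_gt(s@nVoxels, 1e5)
  expect_lt(abs(s@mean - 500), 1)
  expect_lt(abs(s@sd - 25), 1)
})

test_that("thresholds sit k standard deviations from the mean", {
  phs <- generatePhantom(phantomSpec(geometry = smallGeometry(), seed = 5))
  s <- computeReferenceStats(phs$volume, phs$brainMask)
  t2 <- thresholds(s, 2)
  expect_equal(t2@lower, s@mean - 2 * s@sd)
  expect_equal(t2@upper, s@mean + 2 * s@sd)
  th <- fixedThresholds(500, 25, 2)
  expect_equal(c(th@lower, th@upper), c(450, 550))
  expect_equal(c(fixedThresholds(500, 25, 0.5)@lower,
                 fixedThresholds(500, 25, 0.5)@upper), c(487.5, 512.5))
  expect_equal(c(fixedThresholds(0, 1, 2)@lower, fixedThresholds(0, 1, 2)@upper),
               c(-2, 2))
  expect_error(thresholds(s, 0), "k must be")
  expect_error(thresholds(s, -2), "k must be")
})

test_that("automatic brain masking recovers the phantom brain", {
  ph <- generatePhantom(phantomSpec(geometry = smallGeometry(), seed = 9))
  bm <- brainMask(ph$volume, "auto")
  dice <- 2 * sum(bm & ph$brainMask) / (sum(bm) + sum(ph$brainMask))
  expect_gte(dice, 0.99)
  # determinism
  expect_identical(bm, brainMask(ph$volume, "auto"))
  # provided masks pass through verbatim
  expect_identical(brainMask(ph$volume, "provided", mask = ph$brainMask),
                   ph$brainMask)
  # an empty volume has no brain
  flat <- ImageVolume(array(0, dim(ph$brainMask)), smallGeometry())
  expect_error(brainMask(flat, "auto"), "no brain found")
  expect_error(brainMask(ph$volume, "provided",
                         mask = array(FALSE, dim(ph$brainMask))),
               "no brain found")
})

test_that("a volume at the reference mean yields an empty lesion", {
  g <- smallGeometry()
  v <- ImageVolume(array(500, c(10, 48, 48)), g)
  res <- segmentLesion(v, array(TRUE, c(10, 48, 48)), fixedThresholds(500, 25))
  expect_equal(res@nHyper + res@nHypo, 0L)
  expect_equal(lesionVolume(res), 0)
})

test_that("an inserted block is measured by exact voxel arithmetic", {
  g <- ScanGeometry()  # 128 x 128, 15 mm FOV, 0.5 mm slices
  arr <- array(500, c(21, 128, 128))
  arr[9:12, 60:69, 60:69] <- 500 + 5 * 25  # 4 x 10 x 10 block, +5 SD
  v <- ImageVolume(arr, g)
  res <- segmentLesion(v, array(TRUE, dim(arr)), fixedThresholds(500, 25))
  expect_equal(res@nHyper, 400L)
  expect_equal(res@nHypo, 0L)
  expect_equal(lesionVolume(res), 400 * voxelVolume(g))
  expect_equal(round(lesionVolume(res), 3), 2.747)
  # reported volume over voxel volume is always an integer count
  expect_equal(lesionVolume(res) / res@voxelVolumeMm3, 400)
})

test_that("noise-only flagging matches the Gaussian two-tail rate", {
  ph <- generatePhantom(phantomSpec(seed = 31))  # no lesion
  res <- segmentLesion(ph$volume, ph$brainMask, fixedThresholds(500, 25, 2))
  n <- sum(ph$brainMask)
  p <- 2 * (1 - pnorm(2))
  frac <- (res@nHyper + res@nHypo) / n
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("lesion volume is non-increasing in k and translation-equivariant", {
  ph <- generatePhantom(phantomSpec(geometry = smallGeometry(), seed = 13,
                                    lesion = list(targetVolumeMm3 = 2,
                                                  offsetSd = 4)))
  ks <- c(0.5, 1, 1.5, 2, 2.5, 3, 4)
  vols <- sapply(ks, function(k)
    lesionVolume(segmentLesion(ph$volume, ph$brainMask,
                               fixedThresholds(500, 25, k))))
  expect_true(all(diff(vols) <= 0))
  # shifting intensities and the reference mean together changes nothing
  shifted <- ImageVolume(intensities(ph$volume) + 123, geometry(ph$volume))
  m0 <- segmentLesion(ph$volume, ph$brainMask, fixedThresholds(500, 25))@mask
  m1 <- segmentLesion(shifted, ph$brainMask, fixedThresholds(623, 25))@mask
  expect_identical(m0, m1)
})

test_that("the minimum-cluster filter drops isolated voxels only", {
  g <- ScanGeometry(16, 16, c(16, 16), 8, 1)
  arr <- array(500, c(8, 16, 16))
  arr[4, 4, 4] <- 700                    # isolated voxel
  arr[5:6, 8:11, 8:11] <- 700            # 32-voxel block
  v <- ImageVolume(arr, g)
  mask <- array(TRUE, dim(arr))
  all <- segmentLesion(v, mask, fixedThresholds(500, 25))
  expect_equal(all@nHyper, 33L)
  kept <- segmentLesion(v, mask, fixedThresholds(500, 25),
                        minClusterVoxels = 10L)
  expect_equal(kept@nHyper, 32L)
  expect_false(kept@mask[4, 4, 4])
})

test_that("segmentation rejects mismatched shapes", {
  g <- smallGeometry()
  v <- ImageVolume(array(500, c(10, 48, 48)), g)
  expect_error(segmentLesion(v, array(TRUE, c(9, 48, 48)),
                             fixedThresholds(500, 25)), "shape")
})

test_that("batch volumetry recovers known inserted volumes from a manifest", {
  g <- smallGeometry()
  dir <- tempfile("batch")
  dir.create(dir)
  targets <- c(0.6, 1.2, 2.0, 3.0, 4.5, 6.0)
  rows <- lapply(seq_along(targets), function(i) {
    ph <- generatePhantom(phantomSpec(
      geometry = g, seed = 200 + i, subjectId = sprintf("m%02d", i), week = 4,
      lesion = list(targetVolumeMm3 = targets[i], offsetSd = 5)))
    p <- file.path(dir, sprintf("m%02d.nii.gz", i))
    writeVolume(ph$volume, p)
    data.frame(subject_id = sprintf("m%02d", i), scheme_label = "5x20",
               week = 4, modality = "T2", path = p, is_control = 0L,
               trueVoxels = ph$lesionVoxels,
               shell = outerShellVoxels(ph$lesionMask),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  ctrl <- generatePhantom(phantomSpec(geometry = g, seed = 199))
  stats <- computeReferenceStats(ctrl$volume, ctrl$brainMask)
  out <- volumetryBatch(manifest, stats, k = 2, minClusterVoxels = 27L)
  expect_equal(nrow(out), 6L)
  expect_equal(attr(out, "nFailed"), 0L)
  vv <- voxelVolume(g)
  for (i in seq_len(nrow(out))) {
    expect_lt(abs(out$volume_mm3[i] - manifest$trueVoxels[i] * vv),
              manifest$shell[i] * vv)
  }
  # thresholds used are logged into the records
  expect_true(all(out$thr_upper > out$thr_lower))
})

test_that("batch volumetry skips unreadable rows and handles empty manifests", {
  g <- smallGeometry()
  ctrl <- generatePhantom(phantomSpec(geometry = g, seed = 198))
  stats <- computeReferenceStats(ctrl$volume, ctrl$brainMask)
  bad <- data.frame(subject_id = "x", scheme_label = "5x20", week = 4,
                    modality = "T2", path = tempfile(fileext = ".nii.gz"),
                    is_control = 0L, stringsAsFactors = FALSE)
  expect_warning(out <- volumetryBatch(bad, stats), "skipping x")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "nFailed"), 1L)
  empty <- bad[0, ]
  expect_warning(out2 <- volumetryBatch(empty, stats), "no measurement rows")
  expect_equal(nrow(out2), 0L)
})

test_that("mixed-modality manifests use per-modality thresholds", {
  g <- smallGeometry()
  dir <- tempfile("mix")
  dir.create(dir)
  ph2 <- generatePhantom(phantomSpec(geometry = g, seed = 301, brainMean = 500,
                                     brainSd = 25, modality = "T2",
                                     subjectId = "m1", week = 4))
  ph1 <- generatePhantom(phantomSpec(geometry = g, seed = 302, brainMean = 400,
                                     brainSd = 20, modality = "T1post",
                                     subjectId = "m1", week = 4))
  p2 <- file.path(dir, "m1_t2.nii.gz"); writeVolume(ph2$volume, p2)
  p1 <- file.path(dir, "m1_t1.nii.gz"); writeVolume(ph1$volume, p1)
  manifest <- data.frame(
    subject_id = "m1", scheme_label = "5x20", week = 4,
    modality = c("T2", "T1post"), path = c(p2, p1), is_control = 0L,
    stringsAsFactors = FALSE)
  c2 <- generatePhantom(phantomSpec(geometry = g, seed = 303, brainMean = 500,
                                    brainSd = 25, modality = "T2"))
  c1 <- generatePhantom(phantomSpec(geometry = g, seed = 304, brainMean = 400,
                                    brainSd = 20, modality = "T1post"))
  stats <- list(computeReferenceStats(c2$volume, c2$brainMask, "T2"),
                computeReferenceStats(c1$volume, c1$brainMask, "T1post"))
  out <- volumetryBatch(manifest, stats)
  expect_equal(nrow(out), 2L)
  thrT2 <- out[out$modality == "T2", c("thr_lower", "thr_upper")]
  thrT1 <- out[out$modality == "T1post", c("thr_lower", "thr_upper")]
  expect_false(isTRUE(all.equal(unlist(thrT2), unlist(thrT1),
                                check.attributes = FALSE)))
})
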