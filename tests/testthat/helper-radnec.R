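# shared fixtures and independent oracles

# small, fast scan geometry for cohort-level tests
smallGeometry <- function() {
  ScanGeometry(matrixRows = 48L, matrixCols = 48L, fovMm = c(6, 6),
               nSlices = 10L, sliceThicknessMm = 0.5)
}

# thresholds object at stated parameters, bypassing reference estimation
fixedThresholds <- function(mean, sd, k = 2) {
  new("IntensityThresholds", lower = mean - k * sd, upper = mean + k * sd,
      k = k)
}

# brute-force one-way ANOVA F from raw sums of squares
oracleOneWayF <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - grand)^2)
  sse <- sum((y - means[g])^2)
  dfb <- nlevels(g) - 1
  dfe <- length(y) - nlevels(g)
  (ssb / dfb) / (sse / dfe)
}

# brute-force balanced two-way ANOVA (A, B, A:B) F statistics from the
# classical sums-of-squares decomposition; valid for balanced designs,
# where all SS types coincide
oracleTwoWayF <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(unique(table(a, b))) == 1L)  # balanced only
  grand <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mc <- tapply(y, interaction(a, b), mean)
  cellOf <- interaction(a, b)
  r <- table(a, b)[1]
  ssa <- nlevels(b) * r * sum((ma - grand)^2)
  ssb <- nlevels(a) * r * sum((mb - grand)^2)
  ssc <- r * sum((tapply(y, list(a, b), mean) -
                    outer(ma, rep(1, nlevels(b))) -
                    outer(rep(1, nlevels(a)), mb) + grand)^2)
  sse <- sum((y - mc[cellOf])^2)
  dfa <- nlevels(a) - 1
  dfb <- nlevels(b) - 1
  dfab <- dfa * dfb
  dfe <- length(y) - nlevels(a) * nlevels(b)
  mse <- sse / dfe
  c(A = (ssa / dfa) / mse, B = (ssb / dfb) / mse,
    AB = (ssc / dfab) / mse)
}

# balanced measurement table with given cell means
makeMeasurements <- function(schemes, weeks, reps, cellMean = function(s, w) 0,
                             sd = 1, modality = "T2") {
  rows <- expand.grid(scheme = schemes, week = weeks, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  data.frame(
    subject_id = sprintf("%s_r%d", rows$scheme, rows$rep),
    scheme_label = rows$scheme, week = rows$week, modality = modality,
    volume_mm3 = mapply(cellMean, rows$scheme, rows$week) +
      rnorm(nrow(rows), 0, sd),
    stringsAsFactors = FALSE)
}

# outer boundary shell size (voxels) of a 3-D mask
outerShellVoxels <- function(mask) {
  sum(radnec:::.dilate3(mask) & !mask)
}
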