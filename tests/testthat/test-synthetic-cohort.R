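# Synthetic cohort generator: geometry, atlas, ERP structure.

test_that("subject geometry is deterministic and honours zero variance", {
  cfg <- tinyConfig()
  set.seed(5)
  g1 <- makeSubjectGeometry("ASIB", cfg)
  set.seed(5)
  g2 <- makeSubjectGeometry("ASIB", cfg)
  expect_identical(labelData(g1), labelData(g2))

  cfg0 <- tinyConfig(geometrySd = c(ASIB = 0, FXS = 0, LRC = 0))
  set.seed(1)
  a <- makeSubjectGeometry("FXS", cfg0)
  set.seed(99)   # different stream; zero variance must still match
  b <- makeSubjectGeometry("FXS", cfg0)
  expect_identical(labelData(a), labelData(b))
})

test_that("every required tissue label is present with positive count", {
  cfg <- tinyConfig()
  set.seed(2)
  g <- makeSubjectGeometry("LRC", cfg)
  lm <- labelMap(g)
  for (nm in c("background", "white", "gray", "csf", "skull", "scalp"))
    expect_gt(sum(labelData(g) == lm[[nm]]), 0)
})

test_that("unknown group and impossible radii error out", {
  cfg <- tinyConfig()
  expect_error(makeSubjectGeometry("XYZ", cfg), "unknown group")
  bad <- tinyConfig()
  # shell gaps below the minimum resolvable thickness, zero jitter:
  # every redraw fails the ordering test
  bad$geometryMean[["ASIB"]] <- c(brain = 60, csf = 60.5, skull = 61,
                                  scalp = 61.5)
  bad$geometrySd[["ASIB"]] <- 0
  set.seed(3)
  expect_error(makeSubjectGeometry("ASIB", bad), "strictly increasing")
})

test_that("atlas has 18 mutually exclusive ROIs with recorded volumes", {
  geom <- makeLayeredVolume(c(58, 64, 70, 76), 3, 61L)
  atlas <- makeRoiAtlas(geom)
  expect_length(roiNames(atlas), 18L)
  # ROIs are carved out of gray matter only
  gray <- labelData(geom) == labelMap(geom)[["gray"]]
  expect_true(all(gray[labelData(atlas) > 0]))
  # volume bookkeeping equals a brute-force voxel count
  arr <- labelData(atlas)
  for (nm in names(roiNames(atlas))) {
    code <- roiNames(atlas)[[nm]]
    expect_equal(roiVolumes(atlas)[[nm]],
                 sum(arr == code) * voxelSize(atlas)^3)
  }
  expect_equal(sum(roiVolumes(atlas)),
               sum(arr > 0) * voxelSize(atlas)^3)
})

test_that("atlas is symmetric under left-right grid reflection", {
  geom <- makeLayeredVolume(c(58, 64, 70, 76), 3, 61L)
  atlas <- makeRoiAtlas(geom)
  arr <- labelData(atlas)
  expect_identical(arr, arr[rev(seq_len(dim(arr)[1])), , ])
})

test_that("too-small brain errors when ROIs cannot be hosted", {
  geom <- makeLayeredVolume(c(9, 15, 21, 27), 3, 31L)
  expect_error(makeRoiAtlas(geom), "too small")
})

test_that("noiseless ERPs peak where the source spec says", {
  cohort <- .cachedCohort(noiseSd = 0)
  subj <- cohort$subjects[[1]]
  erp <- subj$erp$mother_face
  tt <- timesMs(erp)
  w <- clusterAverage(erp, subj$montage, "all")
  post <- tt > 180 & tt <= 400
  expect_equal(tt[post][which.min(w[post])], 290, tolerance = 4)
  # average reference: channel-wise mean is zero at every sample
  expect_lt(max(abs(colMeans(erpData(erp)))), 1e-12)
  # sample count matches epoch window x sampling rate, channels the montage
  cfg <- cohort$config
  expect_equal(ncol(erpData(erp)),
               diff(cfg$epochWindow) * cfg$samplingRate / 1000)
  expect_equal(nrow(erpData(erp)), length(electrodeNames(subj$montage)))
})

test_that("doubling dipole moments doubles every sample (linearity)", {
  cohort <- .cachedCohort(noiseSd = 0)
  subj <- cohort$subjects[[1]]
  cfg <- cohort$config
  cfg$noiseSd <- 0
  spec <- cohort$sourceSpec
  gain <- gainMatrix(computeLeadField(subj$shell, subj$montage,
                                      as.matrix(spec[, c("x", "y", "z")])))
  e1 <- simulateErp(spec, gain, subj$group, cfg,
                    electrodeNames(subj$montage))
  spec2 <- spec
  spec2$moment_nAm <- 2 * spec2$moment_nAm
  e2 <- simulateErp(spec2, gain, subj$group, cfg,
                    electrodeNames(subj$montage))
  expect_equal(2 * erpData(e1$own_toy), erpData(e2$own_toy),
               tolerance = 1e-12)
})

test_that("a condition missing from the effect sizes errors", {
  cohort <- .cachedCohort(noiseSd = 0)
  cfg <- cohort$config
  cfg$effectSizes <- cfg$effectSizes[-1]
  subj <- cohort$subjects[[1]]
  spec <- cohort$sourceSpec
  gain <- matrix(0, length(electrodeNames(subj$montage)), 3 * nrow(spec))
  expect_error(simulateErp(spec, gain, subj$group, cfg,
                           electrodeNames(subj$montage)),
               "mother_face")
})

test_that("noiseless amplitudes order FXS > LRC > ASIB and faces > toys", {
  cohort <- .cachedCohort(noiseSd = 0)
  pk <- peakTable(cohort)
  byGroup <- tapply(pk$peak_to_peak, pk$group, mean)
  expect_gt(byGroup[["FXS"]], byGroup[["LRC"]])
  expect_gt(byGroup[["LRC"]], byGroup[["ASIB"]])
  cls <- ifelse(grepl("face", pk$condition), "faces", "toys")
  for (g in unique(pk$group)) {
    m <- tapply(pk$peak_to_peak[pk$group == g], cls[pk$group == g], mean)
    expect_gt(m[["faces"]], m[["toys"]])
  }
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  c1 <- makeCohort(tinyConfig(nPerGroup = c(FXS = 2L), seed = 8L),
                   sourceStride = 3L)
  c2 <- makeCohort(tinyConfig(nPerGroup = c(FXS = 2L), seed = 8L),
                   sourceStride = 3L)
  expect_identical(shellRadii(c1$subjects[[1]]$shell),
                   shellRadii(c2$subjects[[1]]$shell))
  expect_identical(erpData(c1$subjects[[2]]$erp$novel_toy),
                   erpData(c2$subjects[[2]]$erp$novel_toy))
})
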