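# eLORETA operator, CDR windowing and ROI summarization.

# compact head model + grid reused across blocks
.zleSetup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sm <- directShell()
    g <- as.matrix(expand.grid(x = seq(-40, 40, by = 10),
                               y = seq(-40, 40, by = 10),
                               z = seq(-40, 40, by = 10)))
    g <- g[sqrt(rowSums(g^2)) < 48, ]
    mont <- placeElectrodes(sm)
    lf <- computeLeadField(sm, mont, g)
    cache <<- list(shell = sm, grid = g, montage = mont, leadField = lf)
    cache
  }
})

test_that("zero iterations give the unit-weight minimum-norm operator", {
  s <- .zleSetup()
  op <- buildEloretaOperator(s$leadField, alpha = 0.05, maxIter = 0L)
  L <- gainMatrix(s$leadField)
  nE <- nrow(L)
  M <- L %*% t(L)
  H <- diag(nE) - matrix(1 / nE, nE, nE)
  C <- M + 0.05 * (sum(diag(M)) / nE) * H
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values)
  Cinv <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  expect_equal(inverseMapping(op), t(L) %*% Cinv, tolerance = 1e-8)
  expect_equal(op@iterations, 0L)
})

test_that("noiseless grid dipoles localize with zero error", {
  s <- .zleSetup()
  op <- buildEloretaOperator(s$leadField, alpha = 1e-4)
  K <- inverseMapping(op)
  L <- gainMatrix(s$leadField)
  nS <- nrow(s$grid)
  set.seed(4)
  hits <- 0L
  n <- 60L
  for (r in seq_len(n)) {
    j <- sample(nS, 1)
    x <- L[, (3 * j - 2):(3 * j)] %*% rnorm(3)
    J <- matrix(K %*% x, nrow = 3)
    hits <- hits + (which.max(colSums(J^2)) == j)
  }
  expect_equal(hits, n)
})

test_that("weights converge to symmetric positive-definite blocks", {
  s <- .zleSetup()
  op <- buildEloretaOperator(s$leadField, alpha = 0.05)
  W <- sourceWeights(op)
  expect_lt(utils::tail(op@trace, 1), 1e-6)
  for (j in sample(dim(W)[3], 10)) {
    expect_equal(W[, , j], t(W[, , j]), tolerance = 1e-10)
    expect_gt(min(eigen(W[, , j], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("non-convergence raises a condition carrying the trace", {
  s <- .zleSetup()
  err <- tryCatch(buildEloretaOperator(s$leadField, alpha = 0.05,
                                       tol = 0, maxIter = 3L),
                  error = identity)
  expect_s3_class(err, "eloretaNonConvergence")
  expect_length(err$trace, 3L)
})

test_that("reconstruction is linear in the data", {
  s <- .zleSetup()
  op <- buildEloretaOperator(s$leadField, alpha = 0.05)
  L <- gainMatrix(s$leadField)
  x <- L[, 4:6] %*% c(5, -2, 1)
  J1 <- inverseMapping(op) %*% x
  J2 <- inverseMapping(op) %*% (2 * x)
  expect_equal(2 * J1, J2, tolerance = 1e-12)
})

test_that("CDR windows are centred, 20 ms long and brute-force checkable", {
  s <- .zleSetup()
  op <- buildEloretaOperator(s$leadField, alpha = 0.05)
  nE <- length(electrodeNames(s$montage))
  set.seed(9)
  # 500 Hz sampling puts the +/- 10 ms edges exactly on samples
  dat <- matrix(rnorm(nE * 350), nE)
  dat <- sweep(dat, 2, colMeans(dat))
  erp <- new("ErpAverage", data = dat,
             channels = electrodeNames(s$montage), samplingRate = 500,
             t0 = -100, condition = "x", group = "y",
             reference = "average")
  cdr <- computeCdr(op, erp, peak = 288)
  # (20 ms x 500 Hz) + 1 samples at integer alignment
  expect_equal(dim(cdr$moments)[3], 11L)
  expect_equal(cdr$window, c(278, 298))
  # brute-force recomputation of the amplitude
  tt <- timesMs(erp)
  sel <- which(tt >= 278 & tt <= 298)
  J <- inverseMapping(op) %*% dat[, sel]
  nS <- nrow(J) / 3
  manual <- rowMeans(matrix(sqrt(colSums(array(J, c(3, nS * length(sel)))^2)),
                            nrow = nS))
  expect_equal(cdr$amplitude, manual, tolerance = 1e-12)
  # zero input reconstructs zero everywhere
  erp0 <- new("ErpAverage", data = matrix(0, nE, 350),
              channels = electrodeNames(s$montage), samplingRate = 500,
              t0 = -100, condition = "x", group = "y",
              reference = "average")
  expect_true(all(computeCdr(op, erp0, peak = 288)$amplitude == 0))
  # window exceeding the record errors
  expect_error(computeCdr(op, erp, peak = 595), "exceeds")
})

test_that("ROI summaries equal brute-force accumulation", {
  cohort <- .cachedCohort(noiseSd = 0)
  subj <- cohort$subjects[[1]]
  atlas <- cohort$atlas
  lf <- subj$leadField
  set.seed(12)
  amp <- runif(nrow(sourcePositions(lf)))
  rs <- summarizeRoi(amp, lf, atlas)
  roi <- sourceRoi(lf)
  for (i in seq_len(nrow(rs))) {
    code <- roiNames(atlas)[[rs$roi[i]]]
    manual <- sum(amp[roi == code]) / roiVolumes(atlas)[[rs$roi[i]]]
    if (rs$n_sources[i] > 0)
      expect_equal(rs$value[i], manual, tolerance = 1e-12)
    else expect_true(is.na(rs$value[i]))
  }
})

test_that("a uniform field gives density-scaled constants and singleton ROIs divide by voxel volume", {
  # hand-built two-ROI atlas: one singleton voxel, one three-voxel ROI
  arr <- array(0L, dim = c(5, 5, 5))
  arr[2, 2, 2] <- 1L
  arr[4, 2:4, 3] <- 2L
  atlas <- new("RoiAtlas", data = arr, voxelSize = 2,
               origin = c(-4, -4, -4),
               roiNames = c(one = 1L, three = 2L),
               roiVolumes = c(one = 8, three = 24))
  sel <- which(arr > 0)
  coords <- voxelCoordinates(atlas)[sel, , drop = FALSE]
  lf <- new("LeadField", gain = matrix(0, 4, 3 * 4),
            sourcePositions = coords, sourceRoi = as.integer(arr[sel]),
            electrodeNames = paste0("e", 1:4), order = 20L,
            reference = "none")
  rs <- summarizeRoi(rep(3, 4), lf, atlas)
  expect_equal(rs$value[rs$roi == "one"], 3 / 8)       # amp / voxel volume
  expect_equal(rs$value[rs$roi == "three"], 9 / 24)    # equal density
})

test_that("mismatched head models degrade the ROI pattern monotonically", {
  cohort <- .cachedCohort(noiseSd = 0)
  subj <- cohort$subjects[[1]]
  atlas <- cohort$atlas
  erp <- subj$erp$mother_face
  pk <- detectN290(clusterAverage(erp, subj$montage, "all"), timesMs(erp),
                   detectP1(clusterAverage(erp, subj$montage, "all"),
                            timesMs(erp)))
  roiVec <- function(op, lf) {
    v <- summarizeRoi(computeCdr(op, erp, pk), lf, atlas)$value
    v[!is.na(v)]
  }
  selfOp <- buildEloretaOperator(subj$leadField, alpha = 0.05)
  ref <- roiVec(selfOp, subj$leadField)
  rs <- numeric(0)
  for (scale in c(1.07, 1.15, 1.3)) {
    sm <- new("ShellModel", center = shellCenter(subj$shell),
              radii = shellRadii(subj$shell) * scale,
              conductivities = shellConductivities(subj$shell),
              order = subj$shell@order, residual = 0)
    mont <- placeElectrodes(sm, cohort$template)
    lf <- computeLeadField(sm, mont, cohort$sourceGrid)
    op <- buildEloretaOperator(lf, alpha = 0.05)
    rs <- c(rs, cor(ref, roiVec(op, lf)))
  }
  expect_true(all(rs < 1))
  expect_true(all(diff(rs) < 0))
})

test_that("middle fusiform activation is larger for faces than toys in every group", {
  cohort <- .cachedCohort(noiseSd = 0)
  for (subj in cohort$subjects) {
    vals <- sapply(c("mother_face", "own_toy"), function(cnd) {
      erp <- subj$erp[[cnd]]
      w <- clusterAverage(erp, subj$montage, "all")
      pk <- detectN290(w, timesMs(erp), detectP1(w, timesMs(erp)))
      op <- buildEloretaOperator(subj$leadField, alpha = 0.05)
      rs <- summarizeRoi(computeCdr(op, erp, pk), subj$leadField,
                         cohort$atlas)
      rs$value[rs$roi == "middle_fusiform"]
    })
    expect_gt(vals[1], vals[2])
  }
})
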