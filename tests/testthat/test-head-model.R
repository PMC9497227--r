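# Conductivity assignment, shell-model fitting, electrode placement and
# the analytic four-shell lead field.

test_that("conductivity assignment maps labels to published values", {
  vol <- sphereVolume(gridDim = 31L, radii = c(16, 20, 24, 28),
                      voxelSize = 2)
  sig <- assignConductivities(vol)
  lm <- labelMap(vol)
  expect_equal(unique(sig[labelData(vol) == lm[["scalp"]]]), 0.35)
  expect_equal(unique(sig[labelData(vol) == lm[["csf"]]]), 1.79)
  expect_equal(unique(sig[labelData(vol) == lm[["skull"]]]), 0.0132)
  expect_equal(unique(sig[labelData(vol) == lm[["background"]]]), 0)
})

test_that("an unmapped label is reported by name", {
  vol <- sphereVolume(gridDim = 31L, radii = c(16, 20, 24, 28))
  arr <- labelData(vol)
  arr[1, 1, 1] <- 99L
  vol@data <- arr
  vol@labels <- c(labelMap(vol), mystery = 99L)
  expect_error(assignConductivities(vol), "mystery")
})

test_that("shell fit recovers exact concentric spheres within half a voxel", {
  vol <- sphereVolume(radii = c(60, 65, 70, 78), voxelSize = 2,
                      gridDim = 91L)
  sm <- fitShellModel(vol)
  expect_equal(unname(shellRadii(sm)), c(60, 65, 70, 78), tolerance = 1 / 60)
  expect_true(all(abs(shellRadii(sm) - c(60, 65, 70, 78)) < 1))
  expect_true(all(diff(shellRadii(sm)) > 0))
  expect_lt(sm@residual, voxelSize(vol))
  # brain shell carries the gray-matter conductivity
  expect_equal(unname(shellConductivities(sm)[["brain"]]), 0.33)
})

test_that("a missing compartment is an error", {
  vol <- sphereVolume(radii = c(60, 65, 70, 78))
  arr <- labelData(vol)
  arr[arr == labelMap(vol)[["csf"]]] <- labelMap(vol)[["skull"]]
  vol@data <- arr
  expect_error(fitShellModel(vol), "compartment")
})

test_that("electrodes land on the scalp radius and clusters are exact", {
  sm <- directShell()
  mont <- placeElectrodes(sm)
  d <- sqrt(rowSums(sweep(electrodePositions(mont), 2,
                          shellCenter(sm))^2))
  expect_equal(d, rep(shellRadii(sm)[["scalp"]], length(d)),
               tolerance = 1e-9)
  cl <- clusterMap(mont)
  expect_length(cl, 12L)
  expect_setequal(cl$PO7, c("E59", "E65", "E66"))
  expect_setequal(cl$P9, c("E57", "E58", "E63", "E64"))
  expect_setequal(cl$TP10, c("E100", "E101", "E107"))
  expect_setequal(cl$PO10, c("E89", "E90", "E94", "E95"))
  # the clusters reference the template electrodes and no others
  expect_true(all(unlist(cl) %in% electrodeNames(mont)))
})

test_that("scaling the shell radii scales every electrode position", {
  sm <- directShell()
  sm2 <- directShell(radii = 1.1 * shellRadii(sm))
  m1 <- placeElectrodes(sm)
  m2 <- placeElectrodes(sm2)
  expect_equal(1.1 * electrodePositions(m1), electrodePositions(m2),
               tolerance = 1e-12)
})

test_that("a template missing a clustered electrode errors", {
  tmpl <- defaultMontageTemplate()
  expect_error(placeElectrodes(directShell(),
                               tmpl[tmpl$name != "E59", ]), "E59")
})

test_that("equal conductivities reduce to the single-sphere closed form", {
  sm <- directShell(cond = c(brain = 0.33, csf = 0.33, skull = 0.33,
                             scalp = 0.33), order = 80L)
  elec <- sphereElectrodes()
  src <- rbind(c(20, -15, 10), c(0, -40, -25), c(5, 5, 50))
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = elec, clusters = list(),
              fiducials = matrix(0, 3, 3))
  lf <- computeLeadField(sm, mont, src)
  for (i in seq_len(nrow(src))) {
    q <- c(30, -10, 25)
    vs <- gainMatrix(lf)[, (3 * i - 2):(3 * i)] %*% q
    vc <- singleSphereDipolePotential(elec, src[i, ], q, 78, sigma = 0.33)
    vc <- vc - mean(vc)
    expect_lt(max(abs(vs - vc)) / max(abs(vc)), 1e-4)
  }
})

test_that("forward gains are linear in the dipole moment", {
  sm <- directShell()
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = sphereElectrodes(), clusters = list(),
              fiducials = matrix(0, 3, 3))
  lf <- computeLeadField(sm, mont, rbind(c(10, 20, -15)))
  G <- gainMatrix(lf)
  m1 <- c(1, 2, 3)
  m2 <- c(-4, 0, 2)
  expect_equal(G %*% (m1 + m2), G %*% m1 + G %*% m2, tolerance = 1e-12)
})

test_that("tangential central dipole is antisymmetric across its normal plane", {
  sm <- directShell()
  # electrode pairs mirrored through the y-z plane
  base <- sphereElectrodes(n = 15)
  mirr <- base
  mirr[, 1] <- -mirr[, 1]
  elec <- rbind(base, mirr)
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:30),
              positions = elec, clusters = list(),
              fiducials = matrix(0, 3, 3))
  lf <- computeLeadField(sm, mont, rbind(c(0, 0, 0)))
  v <- gainMatrix(lf) %*% c(1, 0, 0)   # moment along x
  expect_equal(v[1:15], -v[16:30], tolerance = 1e-8)
})

test_that("gains are invariant under a common rotation", {
  sm <- directShell()
  set.seed(11)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  elec <- sphereElectrodes(n = 25)
  src <- c(15, -25, 30)
  q <- c(12, -7, 4)
  mk <- function(e) new("ElectrodeMontage",
                        names = sprintf("S%02d", seq_len(nrow(e))),
                        positions = e, clusters = list(),
                        fiducials = matrix(0, 3, 3))
  v1 <- gainMatrix(computeLeadField(sm, mk(elec), rbind(src))) %*% q
  v2 <- gainMatrix(computeLeadField(sm, mk(elec %*% t(R)),
                                    rbind(as.numeric(R %*% src)))) %*%
    as.numeric(R %*% q)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("the series is converged by order 40 for mid-depth sources", {
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = sphereElectrodes(), clusters = list(),
              fiducials = matrix(0, 3, 3))
  src <- rbind(c(25, -20, 10))
  g40 <- gainMatrix(computeLeadField(directShell(order = 40L), mont, src))
  g80 <- gainMatrix(computeLeadField(directShell(order = 80L), mont, src))
  expect_lt(max(abs(g40 - g80)), 1e-8 * max(abs(g80)))
})

test_that("lower skull conductivity attenuates scalp potentials", {
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = sphereElectrodes(), clusters = list(),
              fiducials = matrix(0, 3, 3))
  src <- rbind(c(10, -20, 5))
  q <- c(20, 5, -10)
  rms <- function(skull) {
    sm <- directShell(cond = c(brain = 0.33, csf = 1.79, skull = skull,
                               scalp = 0.35))
    v <- gainMatrix(computeLeadField(sm, mont, src)) %*% q
    sqrt(mean(v^2))
  }
  expect_lt(rms(0.0132), rms(0.05))
  expect_lt(rms(0.05), rms(0.33))
})

test_that("sources outside the brain shell are rejected", {
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = sphereElectrodes(), clusters = list(),
              fiducials = matrix(0, 3, 3))
  expect_error(computeLeadField(directShell(), mont, rbind(c(0, 0, 62))),
               "outside the brain shell")
})

test_that("average reference holds column-wise", {
  mont <- new("ElectrodeMontage", names = sprintf("S%02d", 1:40),
              positions = sphereElectrodes(), clusters = list(),
              fiducials = matrix(0, 3, 3))
  lf <- computeLeadField(directShell(), mont,
                         rbind(c(10, 10, 10), c(-30, 5, 0)))
  expect_lt(max(abs(colSums(gainMatrix(lf)))), 1e-10)
})
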